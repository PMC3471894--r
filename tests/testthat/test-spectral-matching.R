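# Precursor filtering, instrument models, similarity scoring and ranked
# annotation.

test_that("precursor filter is strict and monotone in the tolerance", {
  lib <- enumerate_library(default_library_config(classes = "PC"))
  target <- lib[[which(vapply(lib, function(e)
    e$species$short_name == "PC 36:4", logical(1)))[1]]]
  s_exact <- spectrum_record("s1", target$precursor_mz,
                             data.frame(mz = numeric(0), intensity = numeric(0)))
  expect_true(length(precursor_candidates(s_exact, lib, 1.5)) >= 1)

  # a 2.0 mDa error is excluded by the 1.5 mDa accurate-mass rule
  s_off <- spectrum_record("s2", target$precursor_mz + 0.0020,
                           data.frame(mz = numeric(0), intensity = numeric(0)))
  hits <- precursor_candidates(s_off, lib, 1.5)
  expect_false(any(vapply(hits, function(e)
    abs(e$precursor_mz - target$precursor_mz) < 1e-9, logical(1))))

  # exactly-at-tolerance errors are excluded (strict inequality);
  # exactly representable numbers so the boundary is hit precisely
  fake <- target
  fake$precursor_mz <- 700.0
  s_edge <- spectrum_record("s3", 700.25,
                            data.frame(mz = numeric(0), intensity = numeric(0)))
  fake_lib <- structure(list(fake), class = "lipid_library")
  expect_length(precursor_candidates(s_edge, fake_lib, 250), 0)
  expect_length(precursor_candidates(s_edge, fake_lib, 250.001), 1)

  expect_length(precursor_candidates(
    s_exact, structure(list(), class = "lipid_library"), 1.5), 0)

  # widening the tolerance never removes candidates
  set.seed(4)
  for (mz in target$precursor_mz + runif(5, -0.01, 0.01)) {
    s <- spectrum_record("s", mz, data.frame(mz = numeric(0),
                                             intensity = numeric(0)))
    prev <- character(0)
    for (tol in c(0.5, 1.5, 5, 20)) {
      ids <- vapply(precursor_candidates(s, lib, tol),
                    lipidmapp:::entry_id, character(1))
      expect_true(all(prev %in% ids))
      prev <- ids
    }
  }
})

test_that("ion-trap model removes fragments below one third of the precursor", {
  sp <- build_species("PC", list("16:0", "20:4"))
  fr <- predict_fragments(sp)
  trap <- apply_instrument_model(fr, sp$precursor_mz, "iontrap")
  expect_false(any(abs(trap$mz - 184.0733) < 0.01))  # 184 < 782.57/3
  expect_true(all(trap$mz >= sp$precursor_mz / 3))
  qtof <- apply_instrument_model(fr, sp$precursor_mz, "qtof")
  expect_equal(qtof, fr)
  empty <- fr[0, ]
  expect_equal(nrow(apply_instrument_model(empty, 500, "iontrap")), 0)
})

test_that("similarity score matches hand-computed cosine cases", {
  five <- data.frame(mz = c(100, 150, 200, 250, 300),
                     intensity = c(999, 10, 500, 250, 100))
  expect_equal(similarity_score(five, five), 1.0)

  disjoint <- data.frame(mz = five$mz + 5, intensity = five$intensity)
  expect_equal(similarity_score(disjoint, five), 0)

  lib2 <- data.frame(mz = c(100, 200), relative_intensity = c(999, 500))
  exp1 <- data.frame(mz = 100, intensity = 999)
  # cosine of sqrt vectors: sqrt(999) / sqrt(999 + 500)
  expect_equal(similarity_score(exp1, lib2), sqrt(999 / 1499),
               tolerance = 1e-6)
  expect_equal(similarity_score(exp1, lib2), 0.816, tolerance = 1e-3)

  expect_error(similarity_score(five[0, ], five[0, ]), "empty")
  # intensity scaling does not change the cosine
  scaled <- data.frame(mz = five$mz, intensity = five$intensity * 7)
  expect_equal(similarity_score(scaled, five), 1.0)
})

test_that("greedy pairing uses each peak at most once, nearest first", {
  lib <- data.frame(mz = c(100.000, 100.004), relative_intensity = c(999, 999))
  exp1 <- data.frame(mz = 100.002, intensity = 999)
  # one experimental peak can satisfy only one library peak
  sc <- similarity_score(exp1, lib, frag_tol_Da = 0.01)
  expect_equal(sc, cos(pi / 4), tolerance = 0.01)  # 1 of 2 equal dims matched
})

test_that("annotation ranks fragment-supported candidates first", {
  lib <- enumerate_library(default_library_config(
    classes = "PC", chain_pool = c("16:0", "18:0", "18:1", "18:2")))
  # PC 36:2 has two chain compositions (18:1/18:1 and 18:0/18:2):
  # identical precursors, distinguishable only by fragments
  i_a <- which(vapply(lib, function(e)
    lipidmapp:::entry_id(e) == "PC 36:2 (18:1/18:1) [M+H]+", logical(1)))
  i_b <- which(vapply(lib, function(e)
    lipidmapp:::entry_id(e) == "PC 36:2 (18:0/18:2) [M+H]+", logical(1)))
  e_a <- lib[[i_a]]
  s <- spectrum_record("iso", e_a$precursor_mz,
                       data.frame(mz = e_a$fragments$mz,
                                  intensity = e_a$fragments$relative_intensity))
  ann <- annotate_spectra(list(s), lib)
  expect_equal(ann$chains[ann$rank == 1], "18:1/18:1")
  expect_true(all(diff(ann$score) <= 1e-12))  # scores non-increasing with rank
  expect_true(lipidmapp:::entry_id(lib[[i_b]]) %in% paste0(
    ann$name, " (", ann$chains, ") ", ann$adduct))

  # a spectrum far from every entry yields no annotation
  far <- spectrum_record("far", e_a$precursor_mz + 10,
                         data.frame(mz = 184.07, intensity = 999))
  expect_equal(nrow(annotate_spectra(list(far), lib)), 0)
})

test_that("synthetic spectra are recovered at rank 1", {
  lib <- enumerate_library(default_library_config(
    classes = c("PC", "PE", "SM", "lyso-PC")))
  sim <- simulate_spectra(lib, n_spectra = 120, precursor_sd_mda = 0.3,
                          fragment_sd_da = 0.003, dropout = 0.05, seed = 1)
  ann <- annotate_spectra(sim$spectra, lib)
  top <- ann[ann$rank == 1, ]
  m <- merge(sim$truth, top, by = "spectrum_id", all.x = TRUE)
  ok <- !is.na(m$name) & m$name == m$true_name & m$chains == m$true_chains
  expect_gte(mean(ok), 0.95)
})

test_that("head-group-dependent recovery degrades on an ion trap", {
  lib <- enumerate_library(default_library_config(
    classes = c("PC", "SM", "lyso-PC")))
  sim <- simulate_spectra(lib, n_spectra = 250, dropout = 0.35, seed = 1)
  trap_spectra <- lapply(sim$spectra, function(s) {
    fr <- s$fragments[s$fragments$mz >= s$precursor_mz / 3, , drop = FALSE]
    spectrum_record(s$spectrum_id, s$precursor_mz, fr,
                    instrument_mode = "iontrap")
  })
  recovery <- function(spectra) {
    ann <- annotate_spectra(spectra, lib)
    top <- ann[ann$rank == 1, ]
    m <- merge(sim$truth, top, by = "spectrum_id", all.x = TRUE)
    mean(!is.na(m$name) & m$name == m$true_name)
  }
  expect_lt(recovery(trap_spectra), recovery(sim$spectra))
})

test_that("MGF spectra round-trip through write and read", {
  lib <- enumerate_library(default_library_config(classes = "PC",
                                                  chain_pool = c("16:0", "18:1")))
  sim <- simulate_spectra(lib, seed = 5)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sim$spectra, path)
  back <- read_mgf(path)
  expect_length(back, length(sim$spectra))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$spectrum_id, sim$spectra[[i]]$spectrum_id)
    expect_equal(back[[i]]$precursor_mz, sim$spectra[[i]]$precursor_mz,
                 tolerance = 1e-4)
    expect_equal(back[[i]]$fragments$mz, sim$spectra[[i]]$fragments$mz,
                 tolerance = 1e-4)
  }
})
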