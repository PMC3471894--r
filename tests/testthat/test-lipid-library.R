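# In-silico library generation: masses, species assembly, enumeration,
# fragmentation rules and MSP round-trips.

test_that("monoisotopic masses match independent atom sums", {
  expect_equal(monoisotopic_mass(c(H = 2, O = 1)), 18.0106, tolerance = 1e-4)
  expect_identical(monoisotopic_mass(c()), 0)
  # PC 36:4 neutral formula
  pc364 <- c(C = 44, H = 80, N = 1, O = 8, P = 1)
  expect_equal(monoisotopic_mass(pc364), 781.5622, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(pc364), oracle_mass(pc364), tolerance = 1e-4)
  expect_error(monoisotopic_mass(c(C = 1, Xx = 2)), "Xx")
  expect_error(monoisotopic_mass(c(C = -1)), "non-negative")
})

test_that("build_species assembles formulas, names and precursors", {
  sp <- build_species("PC", list("16:0", "20:4"))
  expect_equal(sp$short_name, "PC 36:4")
  expect_equal(sp$formula[c("C", "H", "N", "O", "P")],
               c(C = 44, H = 80, N = 1, O = 8, P = 1))
  sp2 <- build_species("PC", list("16:0", "18:1"))
  expect_equal(sp2$short_name, "PC 34:1")
  expect_equal(sp2$precursor_mz, 760.5851, tolerance = 1e-4)
  # SM totals include the fixed d18:1 sphingoid base
  sm <- build_species("SM", list("16:0"))
  expect_equal(sm$short_name, "SM 34:1")
  expect_equal(sm$formula[c("C", "H", "N", "O", "P")],
               c(C = 39, H = 79, N = 2, O = 6, P = 1))
  # plasmenyl = diacyl minus one O, same H
  pl <- build_species("plasmenyl-PC", list("16:0", "20:4"))
  expect_equal(pl$formula[["O"]], sp$formula[["O"]] - 1)
  expect_equal(pl$formula[["H"]], sp$formula[["H"]])
  expect_error(build_species("lyso-PC", list("16:0", "18:1")), "1 chain")
  expect_error(build_species("TG", list("16:0", "18:1")), "3 chain")
})

test_that("chain validity invariants are enforced", {
  expect_error(acyl_chain(1, 0), "carbons")
  expect_error(acyl_chain(16, -1), "non-negative")
  expect_error(acyl_chain(16, 8), "exceeds")  # floor((16-2)/2) = 7
  expect_silent(acyl_chain(16, 7))
})

test_that("adding one double bond shifts the neutral mass by -H2", {
  for (chains in list(c("18:0", "18:1"), c("16:0", "18:2"))) {
    a <- build_species("PC", as.list(chains))
    bumped <- sub("^(\\d+):(\\d+)$", "\\1", chains[2])
    db <- as.integer(sub("^\\d+:", "", chains[2])) + 1L
    b <- build_species("PC", list(chains[1], paste0(bumped, ":", db)))
    expect_equal(a$neutral_mass - b$neutral_mass, 2.015650, tolerance = 1e-6)
  }
})

test_that("enumeration yields one entry per composition in stable order", {
  cfg <- default_library_config(classes = "PC", chain_pool = c("16:0", "18:1"))
  lib <- enumerate_library(cfg)
  expect_equal(vapply(lib, function(e) e$species$short_name, character(1)),
               c("PC 32:0", "PC 34:1", "PC 36:2"))

  cfg2 <- default_library_config(classes = "PC",
                                 chain_pool = c("16:0", "18:1", "18:2"),
                                 adducts = c("[M+H]+", "[M+Na]+"))
  expect_length(enumerate_library(cfg2), 12)  # 6 compositions x 2 adducts

  expect_length(enumerate_library(default_library_config(classes = "PC",
                                                         chain_pool = character(0))), 0)

  # unordered-pair count k(k+1)/2 for diacyl classes
  for (k in c(2, 4, 5)) {
    pool <- paste0(seq(14, by = 2, length.out = k), ":0")
    lib_k <- enumerate_library(default_library_config(classes = "PE",
                                                      chain_pool = pool))
    expect_length(lib_k, k * (k + 1) / 2)
  }
})

test_that("the default library has no duplicates and passes the mass oracle", {
  lib <- enumerate_library()
  ids <- vapply(lib, lipidmapp:::entry_id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  for (e in lib) {
    expect_equal(monoisotopic_mass(e$species$formula),
                 oracle_mass(e$species$formula), tolerance = 1e-4)
    expect_true(nrow(e$fragments) > 0)
    expect_true(all(e$fragments$mz < e$precursor_mz + 0.5))
    expect_equal(max(e$fragments$relative_intensity), 999)
  }
})

test_that("PC fragmentation rules produce the expected ions", {
  sp <- build_species("PC", list("16:0", "20:4"))
  fr <- predict_fragments(sp)
  # phosphocholine head-group ion (C5H15NO4P+)
  expect_true(any(abs(fr$mz - 184.0733) < 5e-4))
  expect_equal(fr$relative_intensity[which.min(abs(fr$mz - 184.0733))], 999)
  # neutral loss of palmitic acid C16H32O2 (256.2402)
  expect_true(any(abs(fr$mz - (sp$precursor_mz - 256.2402)) < 5e-4))
  # precursor retained as a peak
  expect_true(any(abs(fr$mz - sp$precursor_mz) < 1e-6))
  sp$chains <- list()
  expect_error(predict_fragments(sp), "no acyl chains")
})

test_that("library configs load from JSON and YAML", {
  cfg <- list(PC = list(chain_pool = list("16:0", "18:1")),
              PE = list(chain_pool = list("16:0"),
                        adducts = list("[M+H]+", "[M+Na]+")))
  jp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jp, auto_unbox = TRUE)
  got <- read_library_config(jp)
  expect_length(enumerate_library(got), 3 + 2)
  expect_equal(got$PE$adducts, c("[M+H]+", "[M+Na]+"))
  yp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yp)
  expect_equal(read_library_config(yp), got)
})

test_that("generic MSP spectra load without library metadata", {
  p <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: unknown_1", "PRECURSORMZ: 782.5694", "Num Peaks: 2",
               "184.0733 999", "782.5694 500", "",
               "Name: unknown_2", "PRECURSORMZ: 500.1", "Num Peaks: 0"), p)
  sp <- read_msp_spectra(p, instrument_mode = "iontrap")
  expect_length(sp, 2)
  expect_equal(sp[[1]]$precursor_mz, 782.5694)
  expect_equal(nrow(sp[[1]]$fragments), 2)
  expect_equal(sp[[2]]$spectrum_id, "unknown_2")
  expect_equal(sp[[1]]$instrument_mode, "iontrap")
})

test_that("MSP library round-trips names, precursors and fragments", {
  lib <- enumerate_library(default_library_config(
    classes = c("PC", "PE", "TG", "SM", "plasmenyl-PE")))
  lib <- lib[seq_len(min(100, length(lib)))]
  path <- withr::local_tempfile(fileext = ".msp")
  write_library(lib, path)
  back <- read_library(path)
  expect_length(back, length(lib))
  for (i in seq_along(lib)) {
    expect_equal(back[[i]]$species$short_name, lib[[i]]$species$short_name)
    expect_equal(back[[i]]$precursor_mz, lib[[i]]$precursor_mz,
                 tolerance = 1e-4)
    expect_equal(back[[i]]$fragments$mz, lib[[i]]$fragments$mz,
                 tolerance = 1e-4)
    expect_equal(back[[i]]$fragments$label, lib[[i]]$fragments$label)
  }
  # empty library is a valid (empty) file
  empty_path <- withr::local_tempfile(fileext = ".msp")
  write_library(structure(list(), class = "lipid_library"), empty_path)
  expect_length(read_library(empty_path), 0)
  # malformed input is rejected with a line number
  writeLines(c("Name: PC 34:1", "garbage"), path)
  expect_error(read_library(path), "line")
})
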