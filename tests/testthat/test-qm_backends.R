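# mock parameters used across these tests: flexible-water-like molecule
mock_water_params <- function(charges = c(-0.82, 0.41, 0.41)) {
  spc <- spc_constants()
  mock_qm_params(3,
                 bonds = data.frame(i = 1, j = c(2, 3), b0 = spc$flex_b0,
                                    kb = spc$flex_kb),
                 angles = data.frame(i = 2, j = 1, k = 3,
                                     theta0 = spc$flex_theta0,
                                     ktheta = spc$flex_ktheta),
                 charges = charges)
}

mock_water_geometry <- function() {
  spc <- spc_constants()
  half <- spc$flex_theta0 / 2 * pi / 180
  rbind(c(0, 0, 0),
        c(spc$flex_b0 * sin(half), 0, spc$flex_b0 * cos(half)),
        c(-spc$flex_b0 * sin(half), 0, spc$flex_b0 * cos(half)))
}

test_that("the mock molecule at equilibrium with no point charges is force-free", {
  res <- evaluate_mock_qm(qm_request(c(8, 1, 1), mock_water_geometry()),
                          mock_water_params())
  expect_equal(res$energy, 0, tolerance = 1e-10)
  expect_equal(max(abs(res$qm_forces)), 0, tolerance = 1e-8)
})

test_that("the force on an external point charge obeys Newton's third law", {
  pc <- data.frame(x = 0.5, y = 0.2, z = -0.1, q = 0.3)
  res <- evaluate_mock_qm(qm_request(c(8, 1, 1), mock_water_geometry(),
                                     point_charges = pc),
                          mock_water_params(), "forces")
  expect_equal(colSums(res$mm_response$values), -colSums(res$qm_forces),
               tolerance = 1e-10)
})

test_that("mock forces match finite differences at a random geometry", {
  set.seed(11)
  pos <- mock_water_geometry() + matrix(rnorm(9, sd = 0.01), 3, 3)
  pc <- data.frame(x = rnorm(2, 0.5), y = rnorm(2), z = rnorm(2),
                   q = c(0.4, -0.25))
  params <- mock_water_params()
  res <- evaluate_mock_qm(qm_request(c(8, 1, 1), pos, point_charges = pc),
                          params, "forces")
  e_of <- function(p) evaluate_mock_qm(
    qm_request(c(8, 1, 1), p, point_charges = pc), params, "forces")$energy
  err <- fd_max_error(e_of, res$qm_forces, pos)
  expect_lt(err / max(abs(res$qm_forces)), 1e-6)
})

test_that("total mock force over molecule and point charges vanishes", {
  set.seed(12)
  for (i in 1:10) {
    pos <- mock_water_geometry() + matrix(rnorm(9, sd = 0.02), 3, 3)
    pc <- data.frame(x = rnorm(3, 0.6), y = rnorm(3), z = rnorm(3),
                     q = rnorm(3, sd = 0.4))
    res <- evaluate_mock_qm(qm_request(c(8, 1, 1), pos, point_charges = pc),
                            mock_water_params(), "forces")
    tot <- colSums(res$qm_forces) + colSums(res$mm_response$values)
    expect_lt(max(abs(tot)),
              1e-9 * max(abs(res$qm_forces)) + 1e-12)
  }
})

test_that("unit conversion multiplies from the QM side and divides towards it", {
  tab <- unit_table(length = 0.1, energy = 2625.4996394799,
                    force = 26254.996394799, charge = 1)
  expect_equal(convert_units(1.53, "length", tab, "to_internal"), 0.153)
  expect_equal(convert_units(0.153, "length", tab, "to_qm"), 1.53)
  expect_equal(convert_units(1, "energy", tab, "to_internal"), 2625.4996,
               tolerance = 1e-7)
  x <- c(0.3, -1.7, 42)
  expect_equal(convert_units(convert_units(x, "force", tab, "to_qm"),
                             "force", tab, "to_internal"), x,
               tolerance = 1e-12)
  expect_error(convert_units(1, "dipole", tab), "unknown quantity kind")
  expect_error(unit_table(length = -1), "positive")
})

test_that("request files are deterministic with the documented layout", {
  req <- qm_request(c(6, 1, 1), rbind(c(0, 0, 0), c(0.1, 0, 0),
                                      c(0, 0.1, 0)),
                    is_cap = c(FALSE, FALSE, TRUE))
  f1 <- tempfile(); f2 <- tempfile()
  header <- c("# header", "guess=@GUESS@")
  write_qm_request(req, header, f1)
  write_qm_request(req, header, f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_equal(sum(grepl("^\\$pointcharges", lines)), 0)  # none emitted
  ic <- grep("^\\$coordinates", lines)
  expect_equal(as.integer(strsplit(lines[ic], " ")[[1]][2]), 3)
  expect_match(lines[2], "guess=restart")

  req5 <- qm_request(c(6, 1, 1, 6, 1),
                     matrix(seq(0.1, 1.5, by = 0.1), 5, 3),
                     is_cap = c(rep(FALSE, 3), TRUE, TRUE),
                     point_charges = data.frame(x = 1, y = 2, z = 3, q = 0.4),
                     first_step = TRUE)
  write_qm_request(req5, header, f1)
  lines <- readLines(f1)
  ic <- grep("^\\$coordinates", lines)
  ip <- grep("^\\$pointcharges", lines)
  expect_equal(ip - ic - 1, 5)                 # 3 QM + 2 cap coordinate lines
  expect_match(lines[2], "guess=first")
  unlink(c(f1, f2))
})

test_that("result files round-trip and truncation is reported with the path", {
  res <- structure(list(
    energy = -12.5,
    qm_forces = matrix(rnorm(9), 3, 3),
    mm_response = list(mode = "forces", values = matrix(rnorm(6), 2, 3)),
    updated_qm_charges = c(-0.4, 0.2, 0.2)), class = "qm_result")
  f <- tempfile()
  write_qm_result(res, f)
  back <- read_qm_result(f, 3, 2, "forces")
  expect_equal(back$energy, res$energy, tolerance = 1e-12)
  expect_equal(back$qm_forces, res$qm_forces, tolerance = 1e-12)
  expect_equal(back$mm_response$values, res$mm_response$values,
               tolerance = 1e-12)
  expect_equal(back$updated_qm_charges, res$updated_qm_charges,
               tolerance = 1e-12)

  lines <- readLines(f)
  writeLines(lines[-5], f)   # drop one force line
  expect_error(read_qm_result(f, 3, 2, "forces"), basename(f))
  expect_error(read_qm_result(tempfile("nope"), 3, 2, "forces"),
               "does not exist")
  unlink(f)
})

test_that("the file-protocol path reproduces the in-process mock", {
  params <- mock_water_params()
  units <- unit_table(length = 0.1, energy = 2625.4996394799,
                      force = 26254.996394799, charge = 1)
  exe <- make_fake_qm_executable(params, "forces", tempfile("fakeqm_"),
                                 units)
  backend <- file_qm_backend(exe, header = "# fake", units = units,
                             response_mode = "forces")
  set.seed(13)
  pos <- mock_water_geometry() + matrix(rnorm(9, sd = 0.01), 3, 3)
  pc <- data.frame(x = c(0.5, -0.4), y = c(0.1, 0.3), z = c(0, 0.2),
                   q = c(0.3, -0.3))
  req <- qm_request(c(8, 1, 1), pos, point_charges = pc, first_step = TRUE)
  via_file <- backend$evaluate(req)
  direct <- evaluate_mock_qm(req, params, "forces")
  expect_equal(via_file$energy, direct$energy, tolerance = 1e-10)
  expect_equal(max(abs(via_file$qm_forces - direct$qm_forces)), 0,
               tolerance = 1e-10)
  expect_equal(max(abs(via_file$mm_response$values -
                         direct$mm_response$values)), 0, tolerance = 1e-10)
  unlink(exe)
})

test_that("a failing fake executable surfaces as a backend error", {
  params <- mock_water_params()
  exe <- make_fake_qm_executable(params, "forces", tempfile("fakeqm_"))
  backend <- file_qm_backend(exe, header = "# fake")
  # malformed input: evaluate against a request the mock cannot describe
  bad_req <- qm_request(c(8, 1), rbind(c(0, 0, 0), c(0.1, 0, 0)))
  expect_error(backend$evaluate(bad_req), "exited with status")
  unlink(exe)
})

test_that("the three response modes are mutually consistent", {
  params <- mock_water_params()
  set.seed(14)
  pos <- mock_water_geometry() + matrix(rnorm(9, sd = 0.01), 3, 3)
  pc <- data.frame(x = rnorm(4, 0.6), y = rnorm(4), z = rnorm(4),
                   q = c(0.3, -0.2, 0.15, -0.25))
  req <- qm_request(c(8, 1, 1), pos, point_charges = pc)
  r_forces <- evaluate_mock_qm(req, params, "forces")
  r_field <- evaluate_mock_qm(req, params, "field")
  # field times charge equals the direct force
  expect_equal(pc$q * r_field$mm_response$values,
               r_forces$mm_response$values, tolerance = 1e-12)
  # energies agree across all modes
  r_charges <- evaluate_mock_qm(req, params, "charges")
  expect_equal(r_forces$energy, r_field$energy, tolerance = 1e-12)
  expect_equal(r_forces$energy, r_charges$energy, tolerance = 1e-12)
})
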