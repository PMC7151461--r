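test_that("phantom generation is deterministic and class-conditional", {
  spec <- small_phantom_spec()
  a <- generate_phantom(spec, "pd", 42)
  b <- generate_phantom(spec, "pd", 42)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$data, b$labels$data)
  c2 <- generate_phantom(spec, "pd", 43)
  expect_false(identical(a$volume$data, c2$volume$data))
  expect_identical(list_labels(a$labels), 1:16)
})

test_that("noise-free limit yields constant background + shift inside ROIs", {
  spec <- small_phantom_spec(
    background_sd = 0,
    per_class_params = list(
      control = list(mu_shift = 10, texture_sd = 1e-12, texture_smooth = 0),
      prodromal = list(mu_shift = 20, texture_sd = 1e-12, texture_smooth = 0),
      pd = list(mu_shift = 30, texture_sd = 1e-12, texture_smooth = 0)))
  ph <- generate_phantom(spec, "prodromal", 1)
  inside <- ph$labels$data > 0
  expect_equal(range(ph$volume$data[!inside]), c(100, 100))
  expect_equal(ph$volume$data[inside], rep(120, sum(inside)), tolerance = 1e-9)
})

test_that("geometry invariants are enforced", {
  g <- default_structure_geometry(c(64, 64, 64))
  g$ax[2] <- 1.5
  expect_error(phantom_spec(geometry = g), "semi-axes")
  g <- default_structure_geometry(c(64, 64, 64))
  g$cx[3] <- 2
  expect_error(phantom_spec(geometry = g), "outside grid")
  g <- default_structure_geometry(c(64, 64, 64))
  g$cx[2] <- g$cx[1]; g$cy[2] <- g$cy[1]; g$cz[2] <- g$cz[1]
  expect_error(phantom_spec(geometry = g), "overlap")
  expect_error(cohort_spec(n_per_class = c(1, 1, 1)), "cross-validation")
})

test_that("label map partitions the grid (no voxel in two structures)", {
  ph <- generate_phantom(small_phantom_spec(), "control", 7)
  np <- vapply(1:16, function(L) sum(ph$labels$data == L), numeric(1))
  expect_equal(sum(np) + sum(ph$labels$data == 0), prod(dim(ph$labels$data)))
  expect_true(all(np > 0))
})

test_that("cohort manifest has requested composition and seeded determinism", {
  td <- withr::local_tempdir()
  cs <- cohort_spec(n_per_class = c(2, 1, 3), seed = 11,
                    phantom = small_phantom_spec())
  m <- generate_cohort(cs, file.path(td, "a"))
  expect_equal(nrow(m), 6)
  expect_equal(as.vector(table(factor(m$class, c("control", "prodromal", "pd")))),
               c(2, 1, 3))
  expect_true(all(file.exists(m$volume_path)))
  # same seed reproduces byte-identical scans; different seed does not
  m2 <- generate_cohort(cs, file.path(td, "b"))
  cs3 <- cohort_spec(n_per_class = c(2, 1, 3), seed = 12,
                     phantom = small_phantom_spec())
  m3 <- generate_cohort(cs3, file.path(td, "c"))
  sum1 <- tools::md5sum(m$volume_path)
  expect_identical(unname(sum1), unname(tools::md5sum(m2$volume_path)))
  expect_false(any(unname(sum1) == unname(tools::md5sum(m3$volume_path))))
  expect_identical(names(m3), names(m))
})

test_that("ROI intensity means match the generator's stated moments", {
  # Monte-Carlo moment check, scaled down from the 200-phantom statement to 60
  # 32^3 phantoms per class to stay inside the suite's time budget.
  spec <- small_phantom_spec()
  for (cl in c("control", "pd")) {
    mus <- vapply(1:60, function(s) {
      ph <- generate_phantom(spec, cl, 1000 + s)
      mean(ph$volume$data[ph$labels$data > 0])
    }, numeric(1))
    target <- 100 + spec$per_class_params[[cl]]$mu_shift
    se <- stats::sd(mus) / sqrt(length(mus))
    expect_lt(abs(mean(mus) - target), 3 * se + 1e-9)
  }
})

test_that("increasing mu separation increases the between-class mean gap", {
  spec <- small_phantom_spec()
  roi_mean <- function(cl, s) {
    ph <- generate_phantom(spec, cl, s)
    mean(ph$volume$data[ph$labels$data > 0])
  }
  seeds <- 1:25
  m_ctrl <- vapply(seeds, function(s) roi_mean("control", s), numeric(1))
  m_pd <- vapply(seeds, function(s) roi_mean("pd", 100 + s), numeric(1))
  gap_default <- mean(m_pd) - mean(m_ctrl)
  spec2 <- small_phantom_spec(per_class_params = list(
    control = list(mu_shift = 10, texture_sd = 4, texture_smooth = 0.5),
    prodromal = list(mu_shift = 20, texture_sd = 6, texture_smooth = 1.0),
    pd = list(mu_shift = 50, texture_sd = 8, texture_smooth = 1.5)))
  m_pd2 <- vapply(seeds, function(s) {
    ph <- generate_phantom(spec2, "pd", 100 + s)
    mean(ph$volume$data[ph$labels$data > 0])
  }, numeric(1))
  expect_gt(mean(m_pd2) - mean(m_ctrl), gap_default)
  expect_equal(gap_default, 20, tolerance = 0.1)
})
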