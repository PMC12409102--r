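test_that("NPQt matches its defining ratios", {
  expect_equal(compute_npqt(5.88, 1), 0)
  expect_equal(compute_npqt(2.22, 1), 3, tolerance = 1e-12)
  # state (ql = 0.5, npqt = 2) emitted by the forward model
  fl <- forward_fluorescence(0.5, 2)
  expect_equal(compute_npqt(fl$fm_prime, fl$fo_prime), 2, tolerance = 1e-10)
  expect_error(compute_npqt(1, 1), "Fm'/Fo'")
  expect_error(compute_npqt(-2, 1), "positive")
})

test_that("qL spans the open-closed range and inverts the forward model", {
  expect_equal(compute_ql(fs = 1, fm_prime = 5.88, fo_prime = 1), 1)
  expect_equal(compute_ql(fs = 1.96, fm_prime = 1.96, fo_prime = 0.746), 0)
  fl <- forward_fluorescence(0.5, 2)
  expect_equal(compute_ql(fl$fs, fl$fm_prime, fl$fo_prime), 0.5,
               tolerance = 1e-10)
  expect_equal(fl$fm_prime, 1.96)
  expect_equal(fl$fo_prime, 5.88 / 7.88)
  expect_equal(fl$fs, 1.08088, tolerance = 1e-4)
  expect_error(compute_ql(1, 1, 2), "Fm' must exceed Fo'")
})

test_that("quantum yield formulas honour their closed forms and limits", {
  expect_equal(compute_phi_no(ql = 0, npqt = 0), 1)
  expect_equal(compute_phi_no(ql = 1, npqt = 0), 1 / 5.88)
  expect_equal(compute_phi_no(ql = 0.5, npqt = 2), 1 / 5.44)
  expect_equal(compute_phi_psii(fs = 5.88, fm_prime = 5.88), 0)
  expect_equal(compute_phi_psii(fs = 1, fm_prime = 5.88), 4.88 / 5.88)
  fl <- forward_fluorescence(0.5, 2)
  expect_equal(compute_phi_psii(fl$fs, fl$fm_prime), 0.44853,
               tolerance = 1e-4)
  expect_equal(compute_phi_npq(0.44853, 0.18382), 0.36765, tolerance = 1e-4)
  expect_equal(compute_phi_npq(4.88 / 5.88, 1 / 5.88), 0)
  expect_equal(compute_phi_npq(0, 1), 0)
})

test_that("yields are monotone in their drivers", {
  ql <- seq(0.05, 1, length.out = 40)
  expect_true(all(diff(compute_phi_no(ql, npqt = 1)) < 0))
  npqt <- seq(0, 10, length.out = 40)
  expect_true(all(diff(compute_phi_no(ql = 0.4, npqt)) < 0))
  fs <- seq(0.5, 1.9, length.out = 40)
  expect_true(all(diff(compute_phi_psii(fs, fm_prime = 2)) < 0))
})

test_that("forward/inverse round trip is exact over the state grid", {
  grid <- expand.grid(ql = seq(0.01, 1, length.out = 100),
                      npqt = seq(0, 15, length.out = 100))
  fl <- forward_fluorescence(grid$ql, grid$npqt)
  expect_lt(max(abs(compute_npqt(fl$fm_prime, fl$fo_prime) - grid$npqt)),
            1e-10)
  expect_lt(max(abs(compute_ql(fl$fs, fl$fm_prime, fl$fo_prime) - grid$ql)),
            1e-10)
  # dark-adapted boundary
  dark <- forward_fluorescence(1, 0)
  expect_equal(unlist(dark), c(fs = 1, fm_prime = 5.88, fo_prime = 1))
  # ql = 0 boundary: steady state pinned at the saturation-pulse maximum
  closed <- forward_fluorescence(0, 3)
  expect_equal(closed$fs, closed$fm_prime)
})

test_that("the yield partition is exact for every processed record", {
  tab <- compute_yields(clean_yield_table(200))
  expect_true(all(abs(tab$phi_psii + tab$phi_no + tab$phi_npq - 1) <
                    .Machine$double.eps * 4))
  expect_equal(tab$ql, tab$ql_true, tolerance = 1e-10)
  expect_equal(tab$npqt, tab$npqt_true, tolerance = 1e-10)
})

test_that("compute_yields cross-validates supplied columns against raw", {
  tab <- compute_yields(clean_yield_table(50))
  # consistent supplied columns pass silently
  expect_silent(compute_yields(tab))
  bad <- tab
  bad$ql <- bad$ql + 0.05
  expect_warning(compute_yields(bad), "disagree")
  # recompute = TRUE overwrites
  fixed <- suppressWarnings(compute_yields(bad, recompute = TRUE))
  expect_equal(fixed$ql, tab$ql)
})

test_that("VPD derivation follows Tetens saturation pressure", {
  expect_equal(derive_vpd(25, 100), 0)
  expect_equal(derive_vpd(25, 50), 1.583837, tolerance = 1e-5)
  expect_equal(derive_vpd(35, 60), 2.248999, tolerance = 1e-5)
  expect_error(derive_vpd(25, 101), "rh")
  expect_error(derive_vpd(25, -1), "rh")
})

test_that("qc_filter keeps exactly the positive, unit-sum partitions", {
  tab <- data.frame(phi_psii = c(0.5, 0.7), phi_no = c(0.2, 0.4),
                    phi_npq = c(0.3, -0.1))
  qc <- qc_filter(tab)
  expect_equal(nrow(qc$kept), 1L)
  expect_equal(qc$rejected$qc_reason, "nonpositive_phi_npq")
  expect_equal(sum(qc$log$n), 1L)

  # 100 clean records, 13 corrupted by pushing Fs above Fm'
  tab <- clean_yield_table(100)[, c("fs", "fm_prime", "fo_prime")]
  bad_idx <- c(3, 9, 14, 22, 31, 40, 47, 55, 61, 70, 78, 86, 95)
  tab$fs[bad_idx] <- tab$fm_prime[bad_idx] * 1.05
  qc <- qc_filter(compute_yields(tab))
  expect_equal(nrow(qc$kept), 87L)
  expect_equal(qc$log$n[qc$log$rule == "nonpositive_phi_psii"], 13L)
  expect_setequal(which(!compute_yields(tab)$fs < 0 & seq_len(100) %in% bad_idx),
                  bad_idx)
  expect_equal(sort(as.integer(rownames(qc$rejected))), sort(bad_idx))
})

test_that("qc_filter tolerates external sums only within tolerance", {
  tab <- data.frame(phi_psii = 0.5, phi_no = 0.3, phi_npq = 0.2 + 1e-5)
  expect_equal(nrow(qc_filter(tab)$kept), 0L) |> suppressWarnings()
  expect_equal(nrow(qc_filter(tab, tol = 1e-4)$kept), 1L)
  expect_warning(qc_filter(data.frame(phi_psii = -1, phi_no = 0.5,
                                      phi_npq = 1.5)),
                 "every record")
})
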