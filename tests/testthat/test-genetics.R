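# dense-matrix REML oracle: no eigendecomposition shortcut, direct solves
dense_reml_h2 <- function(y, K) {
  n <- length(y)
  X <- matrix(1, n, 1)
  nll <- function(par) {
    V <- exp(par[1]) * K + exp(par[2]) * diag(n)
    Vi <- solve(V)
    XVX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
    0.5 * ((n - 1) * log(2 * pi) + determinant(V)$modulus +
      log(det(XVX)) + drop(t(y) %*% P %*% y))
  }
  best <- NULL
  for (start in list(c(0, 0), c(-4, 0), c(2, -2))) {
    o <- optim(start, nll, control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  su2 <- exp(best$par[1])
  se2 <- exp(best$par[2])
  su2 / (su2 + se2)
}

test_that("the VanRaden GRM treats clones as self and averages near zero off-diagonal", {
  geno <- simulate_markers(10, 400, seed = 21)
  geno <- rbind(geno, L11 = geno[1, ]) # clone of line 1
  K <- grm_vanraden(geno)
  expect_equal(K["L01", "L11"], K["L01", "L01"], tolerance = 1e-12)
  expect_true(isSymmetric(unname(K)))
  K2 <- grm_vanraden(simulate_markers(22, 5000, seed = 22))
  expect_lt(abs(mean(K2[upper.tri(K2)])), 0.05)
  expect_gt(mean(diag(K2)), 0.8)
  expect_lt(mean(diag(K2)), 1.2)
})

test_that("REML heritability matches a dense-matrix oracle on random small instances", {
  set.seed(23)
  for (rep in 1:2) {
    kin <- fixture_kinship(
      n_lines = 15, n_markers = 100, n_families = 5,
      seed = 30 + rep
    )
    Kr <- kin$K + diag(1e-6, 15)
    for (i in 1:25) {
      h2 <- runif(1, 0.2, 0.9)
      u <- sqrt(h2) * drop(kin$L %*% rnorm(15))
      y <- u + rnorm(15, 0, sqrt(1 - h2))
      mine <- estimate_h2(setNames(y, rownames(Kr)), kin$eK)$h2
      oracle <- dense_reml_h2(y, Kr)
      expect_lt(abs(mine - oracle), 1e-4)
    }
  }
})

test_that("heritability estimates are invariant to shifting and scaling the response", {
  kin <- fixture_kinship(n_lines = 12, n_markers = 80, n_families = 4, seed = 41)
  set.seed(42)
  y <- drop(kin$L %*% rnorm(12)) + rnorm(12, 0, 0.5)
  names(y) <- rownames(kin$K)
  f0 <- estimate_h2(y, kin$eK)
  f_shift <- estimate_h2(y + 100, kin$eK)
  f_scale <- estimate_h2(3 * y, kin$eK)
  expect_equal(f0$h2, f_shift$h2, tolerance = 1e-6)
  expect_equal(f0$h2, f_scale$h2, tolerance = 1e-6)
  expect_equal(f_scale$sigma_u2, 9 * f0$sigma_u2, tolerance = 1e-4)
  expect_gte(f0$lrt_stat, 0)
  expect_gte(f0$loglik_full, f0$loglik_reduced)
})

test_that("with duplicated lines the model reduces to the classical intraclass correlation", {
  # K = I_n (x) J_2: two exact repeats per line, a balanced one-way layout
  n <- 15
  K <- kronecker(diag(n), matrix(1, 2, 2))
  ids <- paste0(rep(sprintf("L%02d", 1:n), each = 2), c("a", "b"))
  dimnames(K) <- list(ids, ids)
  set.seed(43)
  line_eff <- rnorm(n, 0, 2)
  y <- rep(line_eff, each = 2) + rnorm(2 * n)
  names(y) <- ids
  fit <- suppressWarnings(estimate_h2(y, K))
  grp <- rep(seq_len(n), each = 2)
  ms <- anova(lm(y ~ factor(grp)))
  msb <- ms$`Mean Sq`[1]
  msw <- ms$`Mean Sq`[2]
  icc_su <- max((msb - msw) / 2, 0)
  icc_h2 <- icc_su / (icc_su + msw)
  expect_equal(fit$h2, icc_h2, tolerance = 1e-3)
})

test_that("degenerate and null responses are handled honestly", {
  K <- diag(8)
  expect_warning(fit <- estimate_h2(rep(1, 8), K), "constant")
  expect_equal(fit$h2, 0)
  set.seed(44)
  f2 <- estimate_h2(rnorm(8), K)
  expect_equal(f2$h2, 0) # flat likelihood ties to no genetic variance
  td <- tidy(f2)
  expect_equal(td$term, c("sigma_u2", "sigma_e2", "h2"))
  expect_equal(glance(f2)$h2, f2$h2)
})

test_that("null LRT p-values are conservative at the boundary mixture", {
  kin <- fixture_kinship(n_lines = 40, n_markers = 150, n_families = 10, seed = 45)
  set.seed(46)
  pv <- replicate(200, {
    estimate_h2(setNames(rnorm(40), rownames(kin$K)), kin$eK)$p
  })
  expect_lt(mean(pv < 0.05), 0.1)
})

test_that("metabolite heritability reproduces the design-weighted formula", {
  lines <- sprintf("L%02d", 1:22)
  make_met <- function(seed, sd_line = 2, sd_ll = sqrt(2), sd_e = 2) {
    set.seed(seed)
    grid <- expand.grid(
      line = lines, location = c("loc1", "loc2"),
      replicate = c("r1", "r2"), stringsAsFactors = FALSE
    )
    gl <- setNames(rnorm(22, 0, sd_line), lines)
    ll <- matrix(rnorm(44, 0, sd_ll), 22, 2,
      dimnames = list(lines, c("loc1", "loc2"))
    )
    grid$value <- gl[grid$line] + ll[cbind(grid$line, grid$location)] +
      rnorm(nrow(grid), 0, sd_e)
    grid
  }
  # sigma2: line 4, loc:line 2, e 4 -> h2 = 4 / (4 + 1 + 1) = 2/3
  h2s <- vapply(1:60, function(s) metabolite_h2(make_met(s))$h2, numeric(1))
  expect_lt(abs(mean(h2s) - 2 / 3), 0.06)

  one <- make_met(1)
  f <- metabolite_h2(one)
  f2 <- metabolite_h2(transform(one, value = 2 * value))
  expect_equal(f2$h2, f$h2, tolerance = 1e-6)
  expect_equal(f2$sigma2_line, 4 * f$sigma2_line, tolerance = 1e-4)

  null_h2 <- vapply(
    1:20,
    function(s) metabolite_h2(make_met(s, sd_line = 0))$h2, numeric(1)
  )
  expect_lt(mean(null_h2), 0.15)
  expect_error(metabolite_h2(one[one$location == "loc1", ]), "2 locations")
})

test_that("balanced-design EMS closed forms agree with the REML components", {
  lines <- sprintf("L%02d", 1:16)
  set.seed(47)
  grid <- expand.grid(
    line = lines, location = c("loc1", "loc2"),
    replicate = c("r1", "r2"), stringsAsFactors = FALSE
  )
  gl <- setNames(rnorm(16, 0, 3), lines)
  ll <- matrix(rnorm(32, 0, 1.5), 16, 2, dimnames = list(lines, c("loc1", "loc2")))
  loc_eff <- c(loc1 = 1.2, loc2 = -1.2)
  rep_eff <- c(r1 = 0.8, r2 = -0.8)
  grid$value <- gl[grid$line] + ll[cbind(grid$line, grid$location)] +
    loc_eff[grid$location] + rep_eff[grid$replicate] +
    rnorm(nrow(grid), 0, 1)
  fit <- metabolite_h2(grid)
  ms <- anova(lm(
    value ~ location + location:replicate + line + line:location,
    data = grid
  ))
  msq <- setNames(ms$`Mean Sq`, rownames(ms))
  ems_e <- msq[["Residuals"]]
  ems_ll <- (msq[["location:line"]] - ems_e) / 2
  ems_line <- (msq[["line"]] - msq[["location:line"]]) / 4
  expect_equal(fit$sigma2_e, ems_e, tolerance = 1e-3)
  expect_equal(fit$sigma2_loc_line, ems_ll, tolerance = 1e-3)
  expect_equal(fit$sigma2_line, ems_line, tolerance = 1e-3)
})

test_that("permuting lines against the kinship flattens GCoE heritability", {
  kin <- fixture_kinship()
  pl <- fixture_planted_lsm(kin, seed = 51)
  codes <- tibble::tibble(
    transcript_id = colnames(pl$lsm),
    code = rep("u0000", ncol(pl$lsm))
  )
  hn <- suppressWarnings(h2_permutation_null(codes, pl$lsm, kin$K,
    n_perm = 25, seed = 52,
    min_set_size = 5, k_range = 2:4
  ))
  genetic <- hn$real$h2[hn$real$h2 > 0] # planted heritable modules
  expect_gt(median(hn$real$h2), quantile(hn$null$h2, 0.975))
  # determinism
  hn2 <- suppressWarnings(h2_permutation_null(codes, pl$lsm, kin$K,
    n_perm = 25, seed = 52,
    min_set_size = 5, k_range = 2:4
  ))
  expect_identical(hn$null, hn2$null)

  # exchangeable data: real and permuted h2 indistinguishable
  set.seed(53)
  noise <- matrix(rnorm(22 * 30), 22,
    dimnames = list(rownames(kin$K), sprintf("T%03d", 1:30))
  )
  codes_n <- tibble::tibble(
    transcript_id = colnames(noise),
    code = rep("u0000", 30)
  )
  hn0 <- suppressWarnings(h2_permutation_null(codes_n, noise, kin$K,
    n_perm = 25, seed = 54,
    min_set_size = 5, k_range = 2:4
  ))
  both_pos <- c(hn0$real$h2, hn0$null$h2)
  if (sd(both_pos) > 0 && length(unique(hn0$real$h2)) > 1) {
    expect_gt(
      suppressWarnings(wilcox.test(hn0$real$h2, hn0$null$h2)$p.value),
      0.01
    )
  }
})
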