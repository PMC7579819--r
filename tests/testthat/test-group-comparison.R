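test_that("SEM on an empty graph returns variances only", {
  e <- sim_expr(chain_system(4, beta = 0), 200, seed = 3)
  g <- graph_from_edges(colnames(e), character(0), character(0))
  fit <- fit_sem(e, g)
  expect_true(all(fit$lambda_hat == 0))
  expect_equal(unname(fit$delta_hat),
               unname(apply(unclass(e), 2, var)), tolerance = 1e-12)
})

test_that("node-wise SEM estimates equal an independent OLS oracle", {
  sysm <- mediator_system(delete = FALSE)
  e <- sim_expr(sysm, 300, seed = 5)
  g <- graph_from_edges(colnames(e), c("p1", "p2", "m"), c("m", "m", "d"))
  fit <- fit_sem(e, g)
  o1 <- lm(e[, "m"] ~ e[, "p1"] + e[, "p2"])
  expect_lt(abs(fit$lambda_hat["m", "p1"] - coef(o1)[2]), 1e-10)
  expect_lt(abs(fit$lambda_hat["m", "p2"] - coef(o1)[3]), 1e-10)
  o2 <- lm(e[, "d"] ~ e[, "m"])
  expect_lt(abs(fit$lambda_hat["d", "m"] - coef(o2)[2]), 1e-10)
  expect_lt(abs(fit$delta_hat["d"] - summary(o2)$sigma^2), 1e-10)
  # nonzero pattern confined to graph edges
  expect_equal(sum(fit$lambda_hat != 0), 3)
})

test_that("parametric refit recovers the fitted effect matrix", {
  sysm <- mediator_system(delete = FALSE)
  e <- sim_expr(sysm, 800, seed = 6)
  g <- graph_from_edges(colnames(e), c("p1", "p2", "m"), c("m", "m", "d"))
  fit <- fit_sem(e, g)
  # simulate from the fitted system and refit
  sys2 <- true_system(fit$lambda_hat * lower.tri(fit$lambda_hat),
                      sysm$genes, sigma2 = pmax(fit$delta_hat, 1e-6))
  e2 <- sim_expr(sys2, 800, seed = 7)
  fit2 <- fit_sem(e2, g)
  within2se <- abs(fit2$edges$est - fit$edges$est) <= 2 *
    (fit$edges$se + fit2$edges$se)
  expect_gte(mean(within2se), 0.9)
})

test_that("exclusive effect equals the partial-regression coefficient", {
  sysm <- mediator_system(beta_md = 0.5, delete = FALSE)
  e <- sim_expr(sysm, 400, seed = 8)
  g <- graph_from_edges(colnames(e), c("p1", "p2", "m"), c("m", "m", "d"))
  ex <- exclusive_effect(e, "m", "d", g)
  # hand-built normal-equation solve
  X <- cbind(1, e[, "m"], e[, "p1"], e[, "p2"])
  beta <- solve(t(X) %*% X, t(X) %*% e[, "d"])
  expect_lt(abs(ex$est - beta[2]), 1e-10)
  expect_true(ex$significant)
  expect_error(exclusive_effect(e, "p1", "d", g), "not a graph edge")
  g2 <- graph_from_edges(colnames(e), "m", "d")
  expect_error(exclusive_effect(e, "m", "d", g2), "no upstream")
})

test_that("exclusive effect ignores affine changes of uninvolved genes", {
  sysm <- mediator_system(delete = FALSE)
  e <- sim_expr(sysm, 300, seed = 9)
  g <- graph_from_edges(colnames(e), c("p1", "p2", "m"), c("m", "m", "d"))
  ex1 <- exclusive_effect(e, "m", "d", g)
  X <- unclass(e)
  X[, "p1"] <- 3 * X[, "p1"] - 7  # p1 is a regressor: affine is absorbed
  ex2 <- exclusive_effect(expression_matrix(X), "m", "d", g)
  expect_equal(ex1$est, ex2$est, tolerance = 1e-10)
  expect_equal(ex1$se, ex2$se, tolerance = 1e-10)
})

test_that("mediator candidates require more than one upstream effector", {
  ids <- c("a", "m1", "d1")
  g <- graph_from_edges(ids, c("a", "m1"), c("m1", "d1")) # in-degree 1
  e <- sim_expr(chain_system(3, beta = 0.6), 200, seed = 10)
  colnames(e) <- ids
  res <- detect_lost_mediators(e, e, g)
  expect_equal(length(res$candidates), 0)
  expect_equal(nrow(res$lost), 0)
})

test_that("a deleted mediator edge is flagged as lost", {
  sysm <- mediator_system(beta_md = 0.5, delete = TRUE)
  panel <- snp_panel("s1", "chr1", 1L, 0.5)
  geno <- simulate_genotypes(panel, 400, seed = 11)
  e <- simulate_cohorts(sysm, geno, n_cases = 200, n_controls = 200,
                        seed = 12)
  g <- graph_from_edges(colnames(e), c("p1", "p2", "m"), c("m", "m", "d"))
  res <- detect_lost_mediators(cohort_subset(e, "case"),
                               cohort_subset(e, "control"), g)
  expect_equal(res$candidates, "m")
  expect_true(nrow(res$lost) == 1 && res$lost$mediator == "m")
  expect_equal(nrow(res$effects), 2) # both cohorts reported per pair
})

test_that("ridge at nu = 0 reduces to OLS and CV is deterministic", {
  set.seed(13)
  X <- matrix(rnorm(100 * 3), 100)
  y <- X %*% c(0.5, -0.3, 0.2) + rnorm(100)
  b_ridge <- transnet:::.ridge_beta(X, y, 0)
  b_ols <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(max(abs(b_ridge - b_ols)), 1e-8)
  # shrinkage monotone in nu
  expect_lt(sum(transnet:::.ridge_beta(X, y, 10)^2),
            sum(transnet:::.ridge_beta(X, y, 0)^2))
})

test_that("a member that copies the core is predicted almost perfectly", {
  n <- 200
  set.seed(14)
  core <- rnorm(n)
  X <- cbind(core = core, twin = core + rnorm(n, sd = 1e-3))
  rownames(X) <- sprintf("S%03d", 1:n)
  e <- expression_matrix(X)
  g <- graph_from_edges(colnames(X), "core", "twin")
  mod <- make_module("core", "twin")
  pr <- core_prediction_cv(e, mod, g, repeats = 10, seed = 15)
  expect_gte(pr$mean_corr, 0.99)
  expect_lte(pr$mean_mspe, 0.01)
  expect_true(pr$good_predictor)
  pr2 <- core_prediction_cv(e, mod, g, repeats = 10, seed = 15)
  expect_identical(pr, pr2)
})

test_that("known genes are never called novel and mediated members are not flagged", {
  # core -> known -> member (fully mediated)
  ids <- c("core", "known", "member")
  draw <- function() {
    n <- 300
    core <- rnorm(n)
    known <- 0.7 * core + rnorm(n)
    member <- 0.7 * known + rnorm(n)
    e <- expression_matrix(cbind(core = core, known = known,
                                 member = member))
    rownames(e) <- sprintf("S%03d", 1:n)
    e
  }
  flagged <- vapply(1:100, function(r) {
    set.seed(1500 + r)
    g <- graph_from_edges(ids, c("core", "known"), c("known", "member"))
    mod <- make_module("core", c("known", "member"))
    res <- conditional_novel_genes(draw(), draw(), mod, g,
                                   known_genes = "known")
    expect_false("known" %in% res$candidates)
    "member" %in% res$candidates
  }, logical(1))
  expect_lte(mean(flagged), 0.075)
})

test_that("a direct core effect independent of known genes is detected", {
  draw <- function() {
    n <- 300
    core <- rnorm(n)
    known <- 0.7 * core + rnorm(n)
    member <- 0.5 * core + rnorm(n) # direct path, independent of known
    e <- expression_matrix(cbind(core = core, known = known,
                                 member = member))
    rownames(e) <- sprintf("S%03d", 1:n)
    e
  }
  hits <- vapply(1:100, function(r) {
    set.seed(2500 + r)
    g <- graph_from_edges(c("core", "known", "member"),
                          c("core", "core"), c("known", "member"))
    mod <- make_module("core", c("known", "member"))
    "member" %in% conditional_novel_genes(draw(), draw(), mod, g,
                                          known_genes = "known")$candidates
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("edge replication matches a hand-computed regression test", {
  sys <- chain_system(4, beta = 0.8)
  e <- sim_expr(sys, 25, seed = 16)
  g <- graph_from_edges(colnames(e), sprintf("c%02d", 1:3),
                        sprintf("c%02d", 2:4))
  rr <- replicate_edges(g, unclass(e))
  s <- summary(lm(e[, "c02"] ~ e[, "c01"]))
  expect_lt(abs(rr$edges$p[rr$edges$from == "c01"] -
                  s$coefficients[2, 4]), 1e-10)
  # strong chain edges replicate even at n = 25 in most draws
  fr <- vapply(1:50, function(r) {
    e2 <- sim_expr(sys, 25, seed = 1600 + r)
    replicate_edges(g, unclass(e2))$fraction_replicated
  }, numeric(1))
  expect_gte(mean(fr), 0.5)
  # missing genes are excluded and counted
  rr2 <- replicate_edges(g, unclass(e)[, 1:3])
  expect_equal(rr2$n_excluded, 1)
  expect_error(replicate_edges(g, unclass(e)[, 1, drop = FALSE]),
               "no graph edge")
})

test_that("pure-noise replication stays within the FDR bound", {
  g <- graph_from_edges(sprintf("c%02d", 1:10), sprintf("c%02d", 1:9),
                        sprintf("c%02d", 2:10))
  fr <- vapply(1:50, function(r) {
    set.seed(1700 + r)
    noise <- matrix(rnorm(25 * 10), 25,
                    dimnames = list(NULL, sprintf("c%02d", 1:10)))
    replicate_edges(g, noise)$fraction_replicated
  }, numeric(1))
  expect_lte(mean(fr), 0.05 + 3 * sqrt(0.05 * 0.95 / (50 * 9)))
})
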