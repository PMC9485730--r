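test_that("correlation records match a brute-force rank-correlation oracle", {
  expr <- rbind(
    IMM1 = c(1.2, 2.5, 3.1, 4.8, 5.0, 6.3),
    IMM2 = c(6.1, 5.2, 4.4, 3.3, 2.2, 1.8),
    LNCA = c(2.0, 1.1, 3.5, 4.2, 6.6, 5.9),
    LNCB = c(4.4, 4.0, 2.1, 5.5, 1.0, 3.3))
  colnames(expr) <- paste0("S", 1:6)
  out <- screen_ir_lncRNAs(expr, c("IMM1", "IMM2"), c("LNCA", "LNCB"),
                           rho_min = 0, p_max = 1, method = "spearman")
  # brute force: Pearson on ranks
  for (i in seq_len(nrow(out$records))) {
    a <- rank(expr[out$records$immune_gene[i], ])
    b <- rank(expr[out$records$lncRNA[i], ])
    expect_equal(out$records$rho[i],
                 sum((a - mean(a)) * (b - mean(b))) /
                   sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
                 tolerance = 1e-12)
  }
  # and the t-approximation p-value on n-2 df
  r <- out$records$rho[1]
  expect_equal(out$records$p[1],
               2 * pt(-abs(r * sqrt(4 / (1 - r^2))), df = 4),
               tolerance = 1e-12)
})

test_that("a lncRNA copying an immune gene is retained with rho = 1", {
  expr <- rand_expr(3, 10, seed = 4, genes = c("IMM1", "IMM2", "LNC_OTHER"))
  expr <- rbind(expr, LNC_COPY = expr["IMM1", ])
  out <- screen_ir_lncRNAs(expr, c("IMM1", "IMM2"), c("LNC_OTHER", "LNC_COPY"))
  expect_true("LNC_COPY" %in% out$ir_lnc)
  rec <- out$records[out$records$lncRNA == "LNC_COPY" &
                       out$records$immune_gene == "IMM1", ]
  expect_equal(rec$rho, 1)
  expect_equal(rec$p, 0)
})

test_that("independent lncRNAs are almost never retained at default thresholds", {
  retained <- 0L
  n_seeds <- 1000L
  for (s in seq_len(n_seeds)) {
    expr <- rand_expr(6, 28, seed = s,
                      genes = c(paste0("IMM", 1:5), "LNC1"))
    out <- screen_ir_lncRNAs(expr, paste0("IMM", 1:5), "LNC1")
    retained <- retained + (length(out$ir_lnc) > 0L)
  }
  expect_lt(retained / n_seeds, 0.01)
})

test_that("screen thresholds are monotone", {
  expr <- rand_expr(12, 28, seed = 9, genes = c(paste0("IMM", 1:4),
                                                paste0("LNC", 1:8)))
  base <- screen_ir_lncRNAs(expr, paste0("IMM", 1:4), paste0("LNC", 1:8),
                            rho_min = 0.2, p_max = 0.3)
  tighter_rho <- screen_ir_lncRNAs(expr, paste0("IMM", 1:4), paste0("LNC", 1:8),
                                   rho_min = 0.5, p_max = 0.3)
  tighter_p <- screen_ir_lncRNAs(expr, paste0("IMM", 1:4), paste0("LNC", 1:8),
                                 rho_min = 0.2, p_max = 0.01)
  expect_true(all(tighter_rho$ir_lnc %in% base$ir_lnc))
  expect_true(all(tighter_p$ir_lnc %in% base$ir_lnc))
})

test_that("zero-variance genes are excluded with a warning", {
  expr <- rand_expr(3, 10, seed = 2, genes = c("IMM1", "LNC1", "LNC2"))
  expr["LNC2", ] <- 3
  expect_warning(
    out <- screen_ir_lncRNAs(expr, "IMM1", c("LNC1", "LNC2"),
                             rho_min = 0, p_max = 1),
    "zero-variance")
  expect_false("LNC2" %in% out$records$lncRNA)
})

test_that("moderated t at d0 = 0 equals the ordinary pooled-variance t", {
  expr <- rand_expr(50, 12, seed = 31)
  grp <- factor(rep(c("A", "B"), each = 6))
  de <- moderated_t_test(expr, grp, moderation = list(d0 = 0, s0_sq = 1))
  # closed-form two-sample pooled t, computed independently
  for (g in sample(rownames(expr), 10)) {
    x <- expr[g, 1:6]; y <- expr[g, 7:12]
    sp2 <- (5 * var(x) + 5 * var(y)) / 10
    t_ref <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 6 + 1 / 6))
    row <- de[de$gene == g, ]
    expect_equal(row$t, t_ref, tolerance = 1e-12)
    expect_equal(row$p, 2 * pt(-abs(t_ref), df = 10), tolerance = 1e-12)
    expect_equal(row$logFC, mean(x) - mean(y), tolerance = 1e-12)
  }
})

test_that("moderated t at d0 = Inf uses the prior variance everywhere", {
  expr <- rand_expr(20, 10, seed = 13)
  grp <- factor(rep(c("A", "B"), each = 5))
  de <- moderated_t_test(expr, grp, moderation = list(d0 = Inf, s0_sq = 2))
  m1 <- rowMeans(expr[, 1:5]); m2 <- rowMeans(expr[, 6:10])
  expect_equal(de$t, unname((m1 - m2) / sqrt(2 * (2 / 5))), tolerance = 1e-12)
})

test_that("moderated t agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  expr <- rand_expr(200, 14, seed = 77)
  grp <- factor(rep(c("A", "B"), each = 7))
  de <- moderated_t_test(expr, grp)

  design <- model.matrix(~ 0 + grp)
  colnames(design) <- c("A", "B")
  fit <- limma::lmFit(expr, design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(A - B, levels = design))
  fit <- limma::eBayes(fit, trend = FALSE, robust = FALSE)

  expect_equal(de$logFC, unname(fit$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(de$t, unname(fit$t[, 1]), tolerance = 1e-6)
  expect_equal(de$p, unname(fit$p.value[, 1]), tolerance = 1e-6)
  s2 <- (6 * apply(expr[, 1:7], 1, var) + 6 * apply(expr[, 8:14], 1, var)) / 12
  prior <- fit_variance_prior(s2, 12)
  expect_equal(prior$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(prior$s0_sq, fit$s2.prior, tolerance = 1e-6)
})

test_that("identical groups give t = 0 and p = 1", {
  expr <- rand_expr(5, 4, seed = 1)
  expr <- cbind(expr, expr)
  colnames(expr) <- paste0("S", 1:8)
  grp <- factor(rep(c("A", "B"), each = 4))
  de <- moderated_t_test(expr, grp)
  expect_equal(de$logFC, rep(0, 5))
  expect_equal(de$t, rep(0, 5))
  expect_equal(de$p, rep(1, 5))
})

test_that("group size preconditions are enforced", {
  expr <- rand_expr(5, 4, seed = 1)
  expect_error(moderated_t_test(expr, factor(c("A", "B", "B", "B"))),
               class = "irlnc_validation_error")
  expect_error(moderated_t_test(expr, factor(rep("A", 4))),
               class = "irlnc_validation_error")
})

test_that("fc_gate reproduces hand arithmetic and is symmetric/permutation-stable", {
  de <- data.frame(logFC = c(0, 0, 0, 4))
  expect_equal(unname(fc_gate(de)), c(-3, 5))  # mean 1, sd 2

  sym <- data.frame(logFC = c(-2, -1, 0, 1, 2))
  g <- fc_gate(sym)
  expect_equal(unname(g[1]), -unname(g[2]))

  perm <- data.frame(logFC = sample(de$logFC))
  expect_equal(fc_gate(perm), fc_gate(de))

  expect_error(fc_gate(data.frame(logFC = 1)), class = "irlnc_validation_error")
})

test_that("classify_de applies the gate and p filter as stated", {
  de <- data.frame(gene = c("a", "b", "c"),
                   logFC = c(3, 3, 0.1),
                   p = c(0.2, 0.01, 0.01))
  out <- classify_de(de, gate = c(-1, 1))
  expect_identical(out$change, c("NotSig", "Up", "NotSig"))

  # all significant but inside the gate -> all NotSig
  de2 <- data.frame(gene = letters[1:4], logFC = c(0.1, -0.2, 0.3, 0),
                    p = rep(0.001, 4))
  expect_true(all(classify_de(de2, gate = c(-1, 1))$change == "NotSig"))

  # pure function of (logFC, p, gate): permuting rows permutes output
  idx <- c(3, 1, 2)
  expect_identical(classify_de(de[idx, ], gate = c(-1, 1))$change,
                   out$change[idx])
})

test_that("BH adjustment is monotone, bounded below by p, and order-invariant", {
  set.seed(10)
  for (i in 1:10) {
    p <- runif(30)^2
    expr <- rand_expr(30, 8, seed = i)
    de <- moderated_t_test(expr, factor(rep(c("A", "B"), each = 4)))
    expect_true(all(de$adj_p >= de$p - 1e-15))
    ord <- order(de$p)
    expect_true(all(diff(de$adj_p[ord]) >= -1e-15))
    # permutation invariance
    perm <- sample(nrow(expr))
    de_perm <- moderated_t_test(expr[perm, ], factor(rep(c("A", "B"), each = 4)))
    expect_equal(de_perm$adj_p, de$adj_p[perm], tolerance = 1e-12)
  }
})

test_that("reverse immune-gene extraction is monotone and recovers planted links", {
  # planted: IMM0001..3 drive LNC0001..3 at high rho, low noise
  cfg <- sim_config(n_immune_genes = 10L, n_lncRNAs = 10L, n_linked_lnc = 3L,
                    rho_true = 0.95, noise_sd = 0.05, n_de_lnc = 0L,
                    pair_betas = numeric(0), seed = 6L)
  d <- generate_discovery_cohort(cfg)
  imm <- paste0("IMM", sprintf("%04d", 1:10))
  got <- reverse_immune_genes(d$expr, paste0("LNC000", 1:3), imm)
  expect_identical(got, paste0("IMM000", 1:3))

  tighter <- reverse_immune_genes(d$expr, paste0("LNC000", 1:3), imm,
                                  p_max = 1e-4)
  expect_true(all(tighter %in% got))

  # an immune gene equal to a model lncRNA is always retained
  expr2 <- d$expr
  expr2["IMM0010", ] <- expr2["LNC0001", ]
  expect_true("IMM0010" %in%
                reverse_immune_genes(expr2, "LNC0001", imm))

  expect_error(reverse_immune_genes(d$expr, character(0), imm),
               class = "irlnc_validation_error")
})
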