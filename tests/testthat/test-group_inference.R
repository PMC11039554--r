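test_that("glm_compare controls type I error and applies Bonferroni", {
  withr::with_seed(1, {
    n <- 80
    phen <- make_phenotype(n)
    y <- matrix(rnorm(100 * n), 100, n)  # pure noise
  })
  res <- glm_compare(y, phen)
  expect_equal(nrow(res), 100)
  # ~5 uncorrected false positives, ~0 Bonferroni survivors
  expect_lt(sum(res$p < 0.05), 15)
  expect_equal(sum(res$significant), 0)
  # Bonferroni flag is exactly p < alpha/family
  expect_identical(res$significant, res$p < 0.05 / 100)
})

test_that("glm_compare detects a d = 0.8 effect with high power (family 5)", {
  detected <- 0
  n_seeds <- 100
  for (seed in seq_len(n_seeds)) {
    withr::with_seed(seed, {
      phen <- make_phenotype(120)
      y <- matrix(rnorm(5 * 120), 5, 120)
      y[1, phen$group == "patient"] <- y[1, phen$group == "patient"] + 0.8
    })
    res <- glm_compare(y, phen, family = 5)
    if (res$significant[1]) detected <- detected + 1
  }
  # noncentral-t power at d = 0.8, n = 60/60, alpha = 0.01 is ~0.98
  expect_gt(detected / n_seeds, 0.9)
})

test_that("glm_compare matches lm() and encodes the contrast direction", {
  withr::with_seed(2, {
    phen <- make_phenotype(50)
    y <- matrix(rnorm(3 * 50), 3, 50)
    y[2, phen$group == "patient"] <- y[2, phen$group == "patient"] + 1
  })
  res <- glm_compare(y, phen)
  fit <- lm(y[2, ] ~ I(phen$group == "patient") + phen$age + phen$gender)
  sm <- summary(fit)$coefficients[2, ]
  expect_equal(res$estimate[2], unname(sm["Estimate"]), tolerance = 1e-12)
  expect_equal(res$t[2], unname(sm["t value"]), tolerance = 1e-12)
  expect_equal(res$p[2], unname(sm["Pr(>|t|)"]), tolerance = 1e-12)
  expect_gt(res$cohens_d[2], 0)  # patient > control
  expect_equal(sign(res$cohens_d[2]), sign(res$estimate[2]))
})

test_that("degenerate features yield NA, not spurious p values", {
  withr::with_seed(3, {
    phen <- make_phenotype(30)
    y <- matrix(rnorm(2 * 30), 2, 30)
    y[1, ] <- 42
  })
  expect_warning(res <- glm_compare(y, phen), "zero-variance")
  expect_true(is.na(res$p[1]))
  expect_false(res$significant[1])
  expect_false(is.na(res$p[2]))
})

test_that("collinear covariates are a hard error", {
  phen <- make_phenotype(30)
  phen$age2 <- phen$age
  y <- matrix(rnorm(2 * 30), 2, 30)
  expect_error(glm_compare(y, phen, covariates = c("age", "age2")),
               "collinear")
})

test_that("NBS observed statistics equal the identity permutation", {
  withr::with_seed(4, {
    phen <- make_phenotype(40)
    E <- matrix(rnorm(45 * 40), 45, 40)  # 10 regions
  })
  res <- nbs(E, phen, n_perm = 100, seed = 1, edge_p = 0.05)
  # direct per-edge GLM oracle
  X <- model.matrix(~ I(group == "patient") + age + gender, phen)
  t_oracle <- apply(E, 1, function(y) {
    summary(lm(y ~ X - 1))$coefficients[2, 3]
  })
  expect_equal(res$observed_t, t_oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  # identity permutation contributes the observed max size to the null
  obs_max <- if (length(res$increased$components) > 0) {
    max(vapply(res$increased$components, `[[`, integer(1), "size"))
  } else 0L
  expect_equal(res$increased$max_null[1], obs_max)
  # corrected p respects its bounds
  for (cp in res$increased$components) {
    expect_gte(cp$p, 1 / 100)
    expect_lte(cp$p, 1)
  }
})

test_that("NBS components are BFS-connected and subject-order invariant", {
  withr::with_seed(5, {
    phen <- make_phenotype(50)
    E <- matrix(rnorm(105 * 50), 105, 50)  # 15 regions
  })
  # strengthen a 4-node path among patients so a component exists
  pairs <- cbind(i = c(1, 2, 3), j = c(2, 3, 4))
  en <- sprintf("edge_r%03d_r%03d", pairs[, "i"], pairs[, "j"])
  rownames(E) <- iscn:::edge_feature_names(1:15)
  E[en, phen$group == "patient"] <- E[en, phen$group == "patient"] + 3
  res <- nbs(E, phen, n_perm = 100, seed = 2, edge_p = 0.001)
  expect_gte(length(res$increased$components), 1)
  comp <- res$increased$components[[1]]
  g <- igraph::graph_from_edgelist(as.matrix(comp$edges), directed = FALSE)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  expect_equal(igraph::components(g)$no, 1)

  # permuting subject order (with matched phenotype) leaves components alone
  perm <- withr::with_seed(6, sample(50))
  res2 <- nbs(E[, perm], phen[perm, ], n_perm = 100, seed = 2, edge_p = 0.001)
  expect_equal(res2$increased$components[[1]]$edges, comp$edges)
  expect_equal(res2$observed_t, res$observed_t, tolerance = 1e-10)
})

test_that("NBS with no suprathreshold edges returns an empty result", {
  withr::with_seed(7, {
    phen <- make_phenotype(30)
    E <- matrix(rnorm(10 * 30, 0, 1e-3), 10, 30)  # 5 regions, near-null
  })
  res <- nbs(E, phen, n_perm = 100, seed = 3, edge_p = 1e-6)
  expect_length(res$increased$components, 0)
  expect_length(res$decreased$components, 0)
})

test_that("network weight summary counts connections exactly", {
  assignment <- data.frame(region_id = 1:7,
                           network = c("A", "A", "A", "B", "B", "B", "B"))
  # saturated within-A component: all 3 edges
  compA <- list(edges = data.frame(i = c(1, 1, 2), j = c(2, 3, 3)))
  sA <- summarize_networks(compA, assignment)
  expect_equal(sA$weights["A", "A"], 1)
  # 2 edges between A (3 nodes) and B (4 nodes) -> 2/12
  compAB <- list(edges = data.frame(i = c(1, 2), j = c(4, 6)))
  sAB <- summarize_networks(compAB, assignment)
  expect_equal(sAB$weights["A", "B"], 2 / 12)
  expect_equal(sAB$weights["B", "A"], 2 / 12)
  # brute-force recount on a random component
  withr::with_seed(8, {
    pick <- edge_ix <- which(upper.tri(matrix(0, 7, 7)), arr.ind = TRUE)
    pick <- edge_ix[sample(nrow(edge_ix), 8), ]
  })
  comp <- list(edges = data.frame(i = pick[, 1], j = pick[, 2]))
  s <- summarize_networks(comp, assignment)
  lookup <- setNames(assignment$network, assignment$region_id)
  for (a in c("A", "B")) for (b in c("A", "B")) {
    cnt <- sum((lookup[as.character(comp$edges$i)] == a &
                lookup[as.character(comp$edges$j)] == b) |
               (lookup[as.character(comp$edges$i)] == b &
                lookup[as.character(comp$edges$j)] == a))
    na <- sum(assignment$network == a)
    nb <- sum(assignment$network == b)
    denom <- if (a == b) na * (na - 1) / 2 else na * nb
    expect_equal(s$weights[a, b], cnt / denom)
  }
  # unassigned node is a hard error naming it
  bad <- list(edges = data.frame(i = 1, j = 9))
  expect_error(summarize_networks(bad, assignment), "9")
})

test_that("partial correlation: identity, null rate, oracle agreement", {
  withr::with_seed(9, {
    n <- 60
    phen <- make_phenotype(n, groups = rep("patient", n))
    phen$hamd17 <- round(runif(n, 18, 52))
    feats <- matrix(rnorm(200 * n), 200, n)
    feats[1, ] <- phen$hamd17  # identical to the score
  })
  res <- clinical_association(feats, phen)
  expect_equal(res$partial_r[1], 1)
  # null features: ~5% uncorrected false positives
  fp <- mean(res$p[-1] < 0.05)
  expect_lt(fp, 0.11)
  # agreement with the two-step lm oracle on one feature
  rf <- resid(lm(feats[5, ] ~ phen$age + phen$gender))
  rs <- resid(lm(phen$hamd17 ~ phen$age + phen$gender))
  expect_equal(res$partial_r[5], cor(rf, rs), tolerance = 1e-10)
  expect_identical(res$significant, res$p < 0.05 / 200)
})

test_that("clinical_association requires enough scored subjects", {
  phen <- make_phenotype(10)
  phen$hamd17 <- NA_integer_
  phen$hamd17[1:4] <- 20
  feats <- matrix(rnorm(2 * 10), 2, 10)
  expect_error(clinical_association(feats, phen), "too few")
})
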