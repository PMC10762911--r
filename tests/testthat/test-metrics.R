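test_that("AUC equals the Mann-Whitney pairwise count", {
  expect_equal(metric_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(metric_auc(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(metric_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(metric_auc(c(0.1, 0.2), c(1, 1)), "both classes")

  ## pairwise-count oracle with half credit for ties, random instances
  withr::local_seed(77)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(1:3, 1))  # induce ties
    pos <- s[y == 1]
    neg <- s[y == 0]
    oracle <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(metric_auc(s, y), oracle, tolerance = 1e-12)
  }

  ## complement symmetry for tie-free scores
  withr::local_seed(78)
  s <- runif(20)
  y <- c(1, 0, rbinom(18, 1, 0.5))
  expect_equal(metric_auc(s, y) + metric_auc(-s, y), 1)
})

test_that("PR metrics match their step-sum definitions", {
  ## perfect ranking
  pr <- metric_aupr_aps(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(pr$aupr, 1.0)
  expect_equal(pr$aps, 1.0)

  ## single positive ranked last among 4: APS = 0.25
  pr2 <- metric_aupr_aps(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1))
  expect_equal(pr2$aps, 0.25)

  ## brute-force APS oracle on random instances
  withr::local_seed(5)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    y <- c(1, rbinom(n - 1, 1, 0.3))
    s <- runif(n)
    ord <- order(s, decreasing = TRUE)
    ys <- y[ord]
    tp <- cumsum(ys)
    prec <- tp / seq_len(n)
    rec <- tp / sum(y)
    aps_oracle <- sum(diff(c(0, rec)) * prec)
    expect_equal(metric_aupr_aps(s, y)$aps, aps_oracle, tolerance = 1e-12)
  }
  expect_error(metric_aupr_aps(c(0.4, 0.2), c(0, 0)), "positive")
})

test_that("Fmax equals an exhaustive threshold sweep", {
  expect_equal(metric_fmax(c(0.9, 0.8, 0.2), c(1, 1, 0))$fmax, 1.0)

  ## exhaustive enumeration oracle (computed independently per instance)
  withr::local_seed(31)
  for (rep in 1:100) {
    n <- sample(4:25, 1)
    y <- c(1, rbinom(n - 1, 1, 0.4))
    s <- round(runif(n), 2)
    f1_at <- vapply(sort(unique(s)), function(t) {
      pred <- as.integer(s >= t)
      tp <- sum(pred & y)
      if (tp == 0) 0 else 2 * tp / (sum(pred) + sum(y))
    }, numeric(1))
    res <- metric_fmax(s, y)
    expect_equal(res$fmax, max(f1_at), tolerance = 1e-12)
    ## Fmax dominates F1 at any fixed threshold
    expect_gte(res$fmax + 1e-12, f1_at[1])
  }

  ## ties broken toward the larger threshold
  res <- metric_fmax(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(res$threshold, 0.8)
})

test_that("MCC and BACC match closed forms with degenerate conventions", {
  r <- metric_mcc_bacc(tp = 1, fp = 1, tn = 1, fn = 1)
  expect_equal(r$mcc, 0)
  expect_equal(r$bacc, 0.5)
  r2 <- metric_mcc_bacc(tp = 2, fp = 0, tn = 2, fn = 0)
  expect_equal(r2$mcc, 1)
  expect_equal(r2$bacc, 1)
  r3 <- metric_mcc_bacc(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(r3$mcc, 10 / sqrt(600))
  expect_equal(round(r3$mcc, 4), 0.4082)
  expect_equal(r3$bacc, 0.7)
  ## degenerate denominator -> 0 by convention
  expect_equal(metric_mcc_bacc(tp = 0, fp = 0, tn = 5, fn = 3)$mcc, 0)
  ## sign flip under complemented predictions on balanced data
  a <- metric_mcc_bacc(tp = 3, fp = 1, tn = 3, fn = 1)$mcc
  b <- metric_mcc_bacc(tp = 1, fp = 3, tn = 1, fn = 3)$mcc
  expect_equal(a, -b)
})

test_that("metrics are invariant under strictly monotone score transforms", {
  withr::local_seed(41)
  s <- runif(30)
  y <- c(1, 0, rbinom(28, 1, 0.4))
  trans <- function(x) 1 / (1 + exp(-(3 * x - 1)))  # strictly increasing
  expect_equal(metric_auc(trans(s), y), metric_auc(s, y))
  expect_equal(metric_aupr_aps(trans(s), y)$aps, metric_aupr_aps(s, y)$aps)
  expect_equal(metric_fmax(trans(s), y)$fmax, metric_fmax(s, y)$fmax)
})

test_that("pooled evaluation equals concatenated-vector metrics", {
  withr::local_seed(8)
  mk_prof <- function(L, id) {
    structure(matrix(runif(L * 7), L, 7),
              class = c("propensity_profile", "matrix", "array"),
              protein_id = id)
  }
  profiles <- list(A = mk_prof(15, "A"), B = mk_prof(22, "B"))
  labels <- list(A = random_label_set(1, 15, 0.4)[[1]],
                 B = random_label_set(1, 22, 0.4)[[1]])
  ev <- evaluate_predictions(profiles, labels, rep(0.5, 7))
  for (h in 1:7) {
    s <- c(profiles$A[, h], profiles$B[, h])
    y <- c(labels$A[, h], labels$B[, h])
    expect_equal(ev$auc[h], metric_auc(s, y))
  }
  ## duplicating proteins leaves pooled AUC unchanged
  ev2 <- evaluate_predictions(c(profiles, profiles),
                              c(labels, labels), rep(0.5, 7))
  expect_equal(ev2$auc, ev$auc)
  ## single protein: pooled equals per-protein
  ev_one <- evaluate_predictions(profiles["A"], labels["A"], rep(0.5, 7))
  ev_pp <- evaluate_predictions(profiles["A"], labels["A"], rep(0.5, 7),
                                per_protein = TRUE)
  expect_equal(ev_pp$auc, ev_one$auc[match(ev_pp$label, ev_one$label)])
  ## id mismatch is an error
  expect_error(evaluate_predictions(profiles, labels["A"], rep(0.5, 7)),
               "ids differ")
})

test_that("multifunctional-residue evaluation reproduces hand enumeration", {
  ## 6 residues, two MF types:
  ##  type PD = {protein_binding, dna_binding}: residues 1, 2
  ##  type PL = {protein_binding, lipid_binding}: residue 3
  ## residues 4-6 carry at most one function.
  lab <- label_matrix_from(list(
    protein_binding = c(1, 1, 1, 1, 0, 0),
    dna_binding     = c(1, 1, 0, 0, 0, 0),
    lipid_binding   = c(0, 0, 1, 0, 1, 0)
  ))
  sc <- matrix(0.05, 6, 7, dimnames = list(NULL, idr_labels()))
  sc[, "protein_binding"] <- c(0.9, 0.4, 0.8, 0.7, 0.1, 0.2)
  sc[, "dna_binding"]     <- c(0.8, 0.9, 0.2, 0.1, 0.1, 0.1)
  sc[, "lipid_binding"]   <- c(0.1, 0.2, 0.9, 0.3, 0.8, 0.1)
  prof <- structure(sc, class = c("propensity_profile", "matrix", "array"),
                    protein_id = "P")
  thr <- rep(0.5, 7)
  res <- mf_residue_eval(list(P = prof), list(P = lab), thr)
  expect_setequal(res$mf_type,
                  c("protein_binding+dna_binding",
                    "protein_binding+lipid_binding"))
  pd <- res[res$mf_type == "protein_binding+dna_binding", ]
  pl <- res[res$mf_type == "protein_binding+lipid_binding", ]

  ## at thresholds 0.5: residue 1 has both heads >= 0.5 (correct), residue
  ## 2 fails protein_binding (0.4); residue 3 has both >= 0.5 (correct)
  expect_equal(pd$n_residues, 2L)
  expect_equal(pd$n_correct, 1L)
  expect_equal(pl$n_correct, 1L)

  ## hand-enumerated Fmax for type PD: type scores are the per-residue min
  ## of the two heads = (0.8, 0.4, 0.2, 0.1, 0.1, 0.1), truth (1,1,0,0,0,0)
  ## threshold 0.4 -> P = 1, R = 1 -> F1 = 1
  expect_equal(pd$fmax, 1.0)
  ## type PL: min scores (0.1, 0.2, 0.8, 0.3, 0.1, 0.1), truth residue 3
  ## only; threshold 0.8 gives perfect separation
  expect_equal(pl$fmax, 1.0)

  ## a correct residue dropped below threshold flips n_correct
  sc2 <- sc
  sc2[1, "dna_binding"] <- 0.3
  prof2 <- structure(sc2, class = class(prof), protein_id = "P")
  res2 <- mf_residue_eval(list(P = prof2), list(P = lab), thr)
  expect_equal(res2$n_correct[res2$mf_type == "protein_binding+dna_binding"],
               0L)

  ## no MF residues: empty table with a warning
  lab0 <- label_matrix_from(list(protein_binding = c(1, 0, 0)))
  expect_warning(res0 <- mf_residue_eval(list(P = structure(
    matrix(0.5, 3, 7), class = class(prof), protein_id = "P")),
    list(P = lab0), thr), "No multifunctional")
  expect_equal(nrow(res0), 0)
})

test_that("paired bootstrap comparison behaves at the null and converges", {
  withr::local_seed(12)
  mk <- function(L, id) {
    structure(matrix(runif(L * 7), L, 7),
              class = c("propensity_profile", "matrix", "array"),
              protein_id = id)
  }
  profiles <- setNames(lapply(1:6, function(i) mk(20, paste0("P", i))),
                       paste0("P", 1:6))
  labels <- setNames(random_label_set(6, 20, 0.4), paste0("P", 1:6))
  ## identical predictors -> p ~ 1
  res <- compare_predictors(profiles, profiles, labels,
                            n_resamples = 200, seed = 4)
  expect_true(all(res$p_value > 0.5, na.rm = TRUE))
  ## deterministic given seed
  res2 <- compare_predictors(profiles, profiles, labels,
                             n_resamples = 200, seed = 4)
  expect_equal(res, res2)
  expect_error(compare_predictors(profiles[1], profiles[1], labels[1]),
               "two proteins")

  ## convergence: 1000 resamples within 0.05 of a 20000-resample reference
  better <- lapply(profiles, function(p) {
    q <- unclass(p)
    q  # same scores; perturb one head slightly
  })
  profiles_b <- profiles
  profiles_b$P1 <- structure(pmin(unclass(profiles$P1) + 0.05, 1),
                             class = class(profiles$P1), protein_id = "P1")
  p_small <- compare_predictors(profiles, profiles_b, labels,
                                n_resamples = 1000, seed = 9)$p_value[1]
  p_big <- compare_predictors(profiles, profiles_b, labels,
                              n_resamples = 20000, seed = 10)$p_value[1]
  expect_lt(abs(p_small - p_big), 0.05)
})
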