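test_that("generation is deterministic and leaves the global RNG intact", {
  a <- generate_planted_space(plant_config(seed = 99))
  set.seed(123); before <- runif(1)
  set.seed(123)
  b <- generate_planted_space(plant_config(seed = 99))
  after <- runif(1)
  expect_identical(a$set$vectors, b$set$vectors)
  expect_identical(a$set$terms, b$set$terms)
  expect_identical(a$truth, b$truth)
  expect_identical(before, after)  # generator restored the RNG stream

  c_ <- generate_planted_space(plant_config(seed = 100))
  expect_false(identical(a$set$vectors, c_$set$vectors))
})

test_that("infeasible or out-of-range configurations are rejected", {
  expect_error(plant_config(dim = 10, n_groups = 6, n_diagnoses = 12),
               class = "embaudit_config")  # 20 planted directions in 10 dims
  expect_error(plant_config(noise_sd = -1), class = "embaudit_config")
  expect_error(plant_config(case_variant_rate = 1.5),
               class = "embaudit_config")
  expect_error(plant_config(n_groups = 0), class = "embaudit_config")
  # minimal feasible config still generates
  sp <- generate_planted_space(plant_config(dim = 5, n_groups = 1,
                                            n_diagnoses = 2,
                                            n_background = 1, seed = 1))
  expect_s3_class(sp, "planted_space")
  expect_null(sp$truth$probes)  # a single group admits no analogy probe
})

test_that("planted structure: case variants, phrases, and probe closure", {
  sp <- generate_planted_space(plant_config(seed = 41, case_variant_rate = 1))
  # every group term has its capitalized duplicate at rate 1
  expect_true(all(c("group01", "Group01", "diagnosis_01", "Diagnosis_01")
                  %in% sp$set$terms))
  expect_true(any(grepl("_", sp$set$terms)))  # underscore phrases present
  pr <- sp$truth$probes
  expect_true(all(unlist(pr[c("w1", "w2", "w3", "target")]) %in% sp$set$terms))
  # truth ordering is a permutation of the gradient term list
  expect_identical(sort(sp$truth$gradient$ordering),
                   sort(names(sp$truth$gradient_terms$entries)))
  # group -> diagnosis map uses planted vocabulary only
  expect_true(all(sp$truth$group_diagnosis %in%
                    names(sp$truth$diagnoses$entries)))
})

test_that("noise-free spaces give perfect nearest-diagnosis recovery", {
  sp <- generate_planted_space(plant_config(noise_sd = 0, seed = 42))
  es <- unit_normalize(sp$set)
  aud <- batch_audit(es, sp$truth$groups, sp$truth$diagnoses, top_k = 3)
  m <- recovery_metrics(sp, aud)
  expect_equal(m$top1, 1)
  expect_equal(m$mrr, 1)
})

test_that("recovery metrics match closed forms and brute-force enumeration", {
  sp <- generate_planted_space(plant_config(dim = 10, n_groups = 4,
                                            n_diagnoses = 4,
                                            n_background = 1, seed = 43))
  truth <- sp$truth$group_diagnosis
  mk_audit <- function(ranking_per_label) {
    rows <- do.call(rbind, lapply(names(ranking_per_label), function(lb) {
      data.frame(label = lb, rank = seq_along(ranking_per_label[[lb]]),
                 term = ranking_per_label[[lb]], stringsAsFactors = FALSE)
    }))
    rows$score <- 0
    structure(list(rows = rows, metadata = list()), class = "audit_table")
  }
  diags <- names(sp$truth$diagnoses$entries)
  # every truth term ranked 2nd -> top1 0, MRR 1/2
  second <- lapply(names(truth), function(lb)
    c(setdiff(diags, truth[[lb]])[1], truth[[lb]]))
  names(second) <- names(truth)
  m2 <- recovery_metrics(sp, mk_audit(second))
  expect_equal(m2$top1, 0)
  expect_equal(m2$mrr, 0.5)

  # brute force over all orderings of the 4 diagnoses, same list for all labels
  perms <- rbind(1:4, c(2, 1, 3, 4), c(4, 3, 2, 1), c(2, 3, 4, 1), c(3, 1, 4, 2))
  for (i in seq_len(nrow(perms))) {
    ranking <- lapply(names(truth), function(lb) diags[perms[i, ]])
    names(ranking) <- names(truth)
    m <- recovery_metrics(sp, mk_audit(ranking))
    pos <- vapply(names(truth), function(lb)
      which(diags[perms[i, ]] == truth[[lb]]), 0L)
    expect_equal(m$top1, mean(pos == 1L))
    expect_equal(m$mrr, mean(1 / pos))
  }

  alien <- mk_audit(list(not_a_group = diags))
  expect_error(recovery_metrics(sp, alien), class = "embaudit_incomparable")
})

test_that("emitted fixture files parse with both readers and keep the truth", {
  sp <- generate_planted_space(plant_config(noise_sd = 0.1, seed = 44))
  dir <- withr::local_tempdir()
  paths <- write_planted_space(sp, dir)
  g <- read_glove_text(paths[["glove"]])
  w <- read_word2vec_binary(paths[["word2vec"]])
  expect_identical(g$terms, sp$set$terms)
  expect_identical(w$terms, sp$set$terms)
  expect_lt(max(abs(g$vectors - sp$set$vectors)), 1e-6)
  expect_lt(max(abs(w$vectors - sp$set$vectors)), 1e-6)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_identical(truth$gradient$ordering, sp$truth$gradient$ordering)
  expect_identical(truth$config$seed, 44L)
})

test_that("analogy recovery rate agrees with an independently coded simulation", {
  # Reference simulation: same planted model, coded from scratch with direct
  # linear algebra (no package calls on the query path).
  ref_sim <- function(seed) {
    set.seed(seed)
    d <- 50L; ng <- 6L; nd <- 12L; b <- 0.5; ns <- 0.1
    basis <- qr.Q(qr(matrix(rnorm(d * (ng + nd + 2L)), d)))
    gd <- t(basis[, 1:ng]); dd <- t(basis[, ng + 1:nd])
    gv <- gd + b * dd[1:ng, ] + matrix(rnorm(ng * d, sd = ns), ng)
    dv <- dd + matrix(rnorm(nd * d, sd = ns), nd)
    un <- function(m) m / sqrt(rowSums(m^2))
    gv <- un(gv); dv <- un(dv)
    hits <- vapply(2:ng, function(i) {
      q <- gv[1, ] - dv[1, ] + gv[i, ]
      cand <- setdiff(seq_len(nd), 1L)  # w1 excluded
      which.max(as.numeric(dv[cand, ] %*% q)) == match(i, cand)
    }, TRUE)
    mean(hits)
  }
  n_rep <- 60L
  ref <- mean(vapply(1:n_rep, function(s) ref_sim(7000 + s), 0))
  pkg <- mean(vapply(1:n_rep, function(s) {
    sp <- generate_planted_space(plant_config(seed = 8000 + s,
                                              case_variant_rate = 0,
                                              n_background = 10))
    planted_analogy_top1(sp)
  }, 0))
  # two independent binomial estimates of the same recovery probability
  n_trials <- n_rep * 5L
  se <- sqrt(ref * (1 - ref) / n_trials + pkg * (1 - pkg) / n_trials)
  expect_lt(abs(ref - pkg), 1.96 * se + 0.02)
})

test_that("recovery responds to the planted geometry in the right direction", {
  mean_top1 <- function(noise, bias, seeds = 1:12) {
    mean(vapply(seeds, function(s) {
      sp <- generate_planted_space(plant_config(
        noise_sd = noise, bias_magnitude = bias, n_background = 10,
        seed = 5000 + s))
      es <- unit_normalize(sp$set)
      aud <- batch_audit(es, sp$truth$groups, sp$truth$diagnoses, top_k = 1)
      recovery_metrics(sp, aud)$top1
    }, 0))
  }
  lo_noise <- mean_top1(0.05, 0.5)
  hi_noise <- mean_top1(0.6, 0.5)
  expect_gt(lo_noise, hi_noise)          # more noise, worse recovery
  weak_bias <- mean_top1(0.2, 0.1)
  strong_bias <- mean_top1(0.2, 1.0)
  expect_gt(strong_bias, weak_bias)      # stronger planted bias, better
})
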