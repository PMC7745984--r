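test_that("cosine similarity anchors: self 1, orthogonal 0, antipodal -1", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  v <- c(0.3, -0.4, 0.5)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_equal(cosine_similarity(c(1, 2), c(2, 4)), 1)  # scale-free
  expect_equal(cosine_similarity(c(1, 0), c(3, 3)),
               oracle_cos(c(1, 0), c(3, 3)))
  expect_error(cosine_similarity(c(0, 0), c(1, 0)),
               class = "embaudit_degenerate_vector")
})

test_that("analogy with w1 = w3 and exclusion off collapses to w2 at score 1", {
  es <- tiny_set()
  r <- analogy_query(es, "a", "b", "a", exclude_inputs = FALSE, top_k = 2)
  expect_identical(r$term[1], "b")
  expect_equal(r$score[1], 1, tolerance = 1e-9)
})

test_that("analogy recovers planted targets and matches an exhaustive scan", {
  sp0 <- generate_planted_space(plant_config(noise_sd = 0, seed = 21))
  expect_equal(planted_analogy_top1(sp0), 1)

  # full-vocabulary oracle equivalence for one probe, all ranks; a noisy
  # space so no two candidates tie exactly in score
  sp <- generate_planted_space(plant_config(noise_sd = 0.1, seed = 21))
  es <- unit_normalize(sp$set)
  pr <- sp$truth$probes[1, ]
  w1 <- sp$truth$diagnoses$entries[[pr$w1]]
  w2 <- sp$truth$groups$entries[[pr$w2]]
  w3 <- sp$truth$groups$entries[[pr$w3]]
  got <- analogy_query(es, w1, w2, w3, exclude_inputs = FALSE,
                       top_k = length(es$terms))
  q <- oracle_resolve(es, w2) - oracle_resolve(es, w1) + oracle_resolve(es, w3)
  want <- oracle_rank(q, es$terms, es$vectors)
  expect_identical(got$term, want$term)
  expect_equal(got$score, want$score, tolerance = 1e-12)
})

test_that("restriction and exclusion shape the candidate pool", {
  sp <- generate_planted_space(plant_config(noise_sd = 0.05, seed = 22))
  es <- unit_normalize(sp$set)
  pr <- sp$truth$probes[1, ]
  w1 <- sp$truth$diagnoses$entries[[pr$w1]]
  w2 <- sp$truth$groups$entries[[pr$w2]]
  w3 <- sp$truth$groups$entries[[pr$w3]]
  r <- analogy_query(es, w1, w2, w3, restrict = sp$truth$diagnoses,
                     top_k = 50)
  # every returned term comes from the restriction lexicon...
  expect_true(all(r$term %in% names(sp$truth$diagnoses$entries)))
  # ...the probe's own attribute (w1) is excluded by default...
  expect_false(pr$w1 %in% r$term)
  # ...and scores are monotonically non-increasing down the ranking
  expect_true(all(diff(r$score) <= 1e-12))

  expect_error(
    analogy_query(es, w1, w2, w3,
                  restrict = lexicon("only_w1", pr$w1)),
    class = "embaudit_empty_candidates")
  expect_error(analogy_query(es, "absent_token", w2, w3),
               class = "embaudit_oov")
})

test_that("nearest_in_lexicon matches an independent exhaustive sort", {
  sp <- generate_planted_space(plant_config(noise_sd = 0.1, seed = 23))
  es <- unit_normalize(sp$set)
  diag_lex <- sp$truth$diagnoses
  for (lab in names(sp$truth$groups$entries)[1:3]) {
    got <- nearest_in_lexicon(es, sp$truth$groups$entries[[lab]], diag_lex,
                              top_k = length(diag_lex))
    lv <- oracle_resolve(es, sp$truth$groups$entries[[lab]])
    cand <- t(vapply(names(diag_lex$entries),
                     function(d) oracle_resolve(es, diag_lex$entries[[d]]),
                     numeric(es$dim)))
    want <- oracle_rank(lv, rownames(cand), cand)
    expect_identical(got$term, want$term)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }

  # lexicon containing only the label, self-exclusion off -> itself at 1.0
  es2 <- tiny_set()
  r <- nearest_in_lexicon(es2, "a", lexicon("self", "a"), top_k = 1,
                          exclude_self = FALSE)
  expect_identical(r$term, "a")
  expect_equal(r$score, 1, tolerance = 1e-9)
  expect_error(nearest_in_lexicon(es2, "a", lexicon("self", "a")),
               class = "embaudit_empty_candidates")
})

test_that("batch audits are row-wise identical to per-label calls", {
  sp <- generate_planted_space(plant_config(noise_sd = 0.1, seed = 24))
  es <- unit_normalize(sp$set)
  aud <- batch_audit(es, sp$truth$groups, sp$truth$diagnoses, top_k = 3)
  expect_s3_class(aud, "audit_table")
  expect_identical(unique(aud$rows$label), names(sp$truth$groups$entries))
  for (lab in unique(aud$rows$label)) {
    direct <- nearest_in_lexicon(es, sp$truth$groups$entries[[lab]],
                                 sp$truth$diagnoses, top_k = 3)
    rows <- aud$rows[aud$rows$label == lab, ]
    expect_identical(rows$term, direct$term)
    expect_equal(rows$score, direct$score, tolerance = 1e-12)
    expect_identical(rows$rank, seq_len(3L))
  }
  expect_identical(aud$metadata$mode, "nearest")
  expect_identical(aud$metadata$dim, es$dim)

  single <- batch_audit(es, lexicon("one", "group01"), sp$truth$diagnoses)
  expect_identical(unique(single$rows$label), "group01")

  oov <- lexicon("ghosts", c("nope1", "nope2"))
  expect_error(batch_audit(es, oov, sp$truth$diagnoses),
               class = "embaudit_empty_audit")
})

test_that("analogy-mode batch audit applies the template to every label", {
  sp <- generate_planted_space(plant_config(noise_sd = 0, seed = 25))
  es <- unit_normalize(sp$set)
  pr <- sp$truth$probes
  labels <- lexicon("probe_groups",
                    sp$truth$groups$entries[unique(pr$w3)])
  tmpl <- list(w1 = sp$truth$diagnoses$entries[[pr$w1[1]]],
               w2 = sp$truth$groups$entries[[pr$w2[1]]],
               restrict = sp$truth$diagnoses)
  aud <- batch_audit(es, labels, tmpl, top_k = 1)
  expect_identical(aud$metadata$mode, "analogy")
  got <- stats::setNames(aud$rows$term[aud$rows$rank == 1], aud$rows$label)
  expect_identical(got[pr$w3], stats::setNames(pr$target, pr$w3))
})

test_that("the two score rules rank identically but score differently", {
  sp <- generate_planted_space(plant_config(noise_sd = 0.1, seed = 26))
  es <- unit_normalize(sp$set)
  pr <- sp$truth$probes[1, ]
  w1 <- sp$truth$diagnoses$entries[[pr$w1]]
  w2 <- sp$truth$groups$entries[[pr$w2]]
  w3 <- sp$truth$groups$entries[[pr$w3]]
  a <- analogy_query(es, w1, w2, w3, restrict = sp$truth$diagnoses,
                     top_k = 5, score_rule = "3cosadd")
  b <- analogy_query(es, w1, w2, w3, restrict = sp$truth$diagnoses,
                     top_k = 5, score_rule = "pairwise")
  expect_identical(a$term, b$term)          # retrieval is always 3CosAdd
  expect_false(isTRUE(all.equal(a$score, b$score)))
  # pairwise scores are cosines to w3 itself
  v3 <- oracle_resolve(es, w3)
  d1 <- oracle_resolve(es, sp$truth$diagnoses$entries[[b$term[1]]])
  expect_equal(b$score[1], oracle_cos(v3, d1), tolerance = 1e-12)
})

test_that("audit tables serialize to TSV and JSON with metadata", {
  sp <- generate_planted_space(plant_config(noise_sd = 0, seed = 27))
  es <- unit_normalize(sp$set)
  aud <- batch_audit(es, sp$truth$groups, sp$truth$diagnoses, top_k = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_audit(aud, tsv)
  write_audit(aud, jsn)
  back <- utils::read.delim(tsv)
  expect_identical(names(back), c("label", "rank", "term", "score"))
  expect_equal(nrow(back), nrow(aud$rows))
  parsed <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  expect_identical(parsed$metadata$mode, "nearest")
  expect_true(nzchar(parsed$metadata$against$hash))
})
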