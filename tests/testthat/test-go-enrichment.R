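# OBO parsing, true-path propagation, Fisher term tests, enrichment.

test_that("the OBO reader handles chains, obsolete terms and unknown tags", {
  dag <- parse_obo(c(chain_obo(),
                     "[Term]", "id: GO:1000009", "name: gone",
                     "namespace: molecular_function",
                     "is_obsolete: true",
                     "created_by: someone",       # unknown tag, ignored
                     ""))
  expect_equal(nrow(dag$terms), 4L)
  expect_equal(sum(dag$terms$obsolete), 1L)
  expect_equal(dag$parents[["GO:1000003"]], "GO:1000002")
  expect_equal(dag$closure[["GO:1000003"]],
               c("GO:1000001", "GO:1000002", "GO:1000003"))
  # obsolete terms reject annotations during propagation
  expect_warning(
    prop <- propagate_true_path(dag, list(p = "GO:1000009")), "obsolete")
  expect_equal(prop$p, character(0))
})

test_that("OBO cycles abort with the offending cycle listed", {
  cyc <- c("[Term]", "id: GO:1000001", "name: a",
           "namespace: molecular_function", "is_a: GO:1000002 ! b", "",
           "[Term]", "id: GO:1000002", "name: b",
           "namespace: molecular_function", "is_a: GO:1000001 ! a", "")
  expect_error(parse_obo(cyc), "cycle")
})

test_that("random DAGs parse with the generator's exact edge count", {
  for (seed in 1:4) {
    ro <- random_obo(30L, seed)
    dag <- parse_obo(ro$lines)
    expect_equal(sum(lengths(dag$parents)), sum(lengths(ro$parents)))
    expect_setequal(dag$terms$id, ro$ids)
  }
})

test_that("true-path propagation closes annotation sets and is idempotent", {
  dag <- parse_obo(chain_obo())
  prop <- propagate_true_path(dag, list(p1 = "GO:1000003"))
  expect_equal(prop$p1, c("GO:1000001", "GO:1000002", "GO:1000003"))
  # already-closed input is unchanged
  expect_equal(propagate_true_path(dag, prop), prop)
  # unknown terms: warn and skip, or error on request
  expect_warning(propagate_true_path(dag, list(p = "GO:9999999")),
                 "unknown")
  expect_error(propagate_true_path(dag, list(p = "GO:9999999"),
                                   on_unknown = "error"), "unknown")
})

test_that("propagation agrees with a breadth-first ancestor oracle", {
  for (seed in 1:3) {
    ro <- random_obo(40L, seed)
    dag <- parse_obo(ro$lines)
    set.seed(seed + 100)
    direct <- lapply(1:20, function(i) sample(ro$ids, sample(1:4, 1)))
    names(direct) <- sprintf("p%02d", 1:20)
    prop <- propagate_true_path(dag, direct)
    for (p in names(direct)) {
      manual <- sort(unique(unlist(
        lapply(direct[[p]], oracle_ancestors, parents = ro$parents))))
      expect_equal(prop[[p]], manual)
    }
  }
})

test_that("Fisher term test equals brute-force enumeration and closed forms", {
  # study == universe -> p = 1 always; zero observed -> p = 1
  expect_equal(fisher_term_test(3, 10, 3, 10), 1)
  expect_equal(fisher_term_test(0, 5, 8, 20), 1)
  # spec worked example: 5 of 10 study, 5 of 20 universe
  expect_equal(fisher_term_test(5, 10, 5, 20),
               oracle_fisher_enum(5, 10, 5, 20), tolerance = 1e-12)
  # margin sweep
  set.seed(5)
  for (i in 1:50) {
    u <- sample(4:25, 1)
    s <- sample(1:u, 1)
    a <- sample(1:u, 1)
    o <- sample(max(0, s + a - u):min(s, a), 1)
    expect_equal(fisher_term_test(o, s, a, u),
                 oracle_fisher_enum(o, s, a, u), tolerance = 1e-12)
  }
  expect_error(fisher_term_test(6, 5, 8, 20), "exceeds")
  expect_error(fisher_term_test(2, 25, 8, 20), "universe")
})

test_that("a planted enriched term ranks first and passes the q filter", {
  # universe of 2500, study of 500; one leaf at 3x the background rate in
  # the study, all other leaves at uniform rates
  dag <- parse_obo(random_obo(25L, 7)$lines)
  set.seed(7)
  ids <- dag$terms$id
  leaves <- ids[!ids %in% unlist(dag$parents)]
  target <- leaves[1L]
  other <- setdiff(ids, target)
  universe_acc <- sprintf("u%04d", 1:2500)
  study_acc <- universe_acc[1:500]
  direct <- lapply(universe_acc, function(a) {
    terms <- other[runif(length(other)) < 0.05]
    p_t <- if (a %in% study_acc) 0.30 else 0.10
    if (runif(1) < p_t) terms <- c(terms, target)
    terms
  })
  names(direct) <- universe_acc
  vp <- as_proteome(protein_table(universe_acc,
                                  rep("Genus", length(universe_acc)),
                                  go_terms = direct))
  rows <- enrich(study_acc, vp, dag)
  top <- rows[which.min(rows$p), ]
  expect_equal(top$go_id, target)
  expect_true(top$significant_q)
  expect_true(all(rows$q >= rows$p))
})

test_that("enrichment output respects parent dominance, BH shape and determinism", {
  dag <- parse_obo(random_obo(30L, 9)$lines)
  set.seed(9)
  ids <- dag$terms$id
  universe_acc <- sprintf("u%03d", 1:400)
  direct <- lapply(universe_acc, function(a) ids[runif(length(ids)) < 0.06])
  names(direct) <- universe_acc
  vp <- as_proteome(protein_table(universe_acc,
                                  rep("Genus", length(universe_acc)),
                                  go_terms = direct))
  study <- sample(universe_acc, 120)
  rows <- enrich(study, vp, dag)
  # parent dominance after propagation, in universe and study counts
  lookup <- setNames(seq_len(nrow(rows)), rows$go_id)
  for (id in rows$go_id) {
    for (parent in dag$parents[[id]]) {
      if (parent %in% rows$go_id) {
        expect_gte(rows$annotated[lookup[[parent]]],
                   rows$annotated[lookup[[id]]])
        expect_gte(rows$observed[lookup[[parent]]],
                   rows$observed[lookup[[id]]])
      }
    }
  }
  # q in [p, 1], monotone along the p-ranking within the namespace
  expect_true(all(rows$q >= rows$p & rows$q <= 1))
  ord <- order(rows$p)
  expect_true(all(diff(rows$q[ord]) >= -1e-12))
  # observed <= annotated and <= study size; expected as defined
  expect_true(all(rows$observed <= rows$annotated))
  expect_true(all(rows$observed <= length(study)))
  # no RNG: identical calls give identical tables
  expect_identical(rows, enrich(study, vp, dag))
  # empty study -> zero rows with a warning
  expect_warning(none <- enrich(character(0), vp, dag), "empty study")
  expect_equal(nrow(none), 0L)
})

test_that("raw Fisher p-values are calibrated on null study subsets", {
  # uniform universe annotation, random study subsets: across replicates
  # the fraction of term tests with p < alpha should be close to alpha
  dag <- parse_obo(random_obo(20L, 13)$lines)
  ids <- dag$terms$id
  set.seed(13)
  hits <- 0L
  total <- 0L
  for (rep in 1:200) {
    universe_acc <- sprintf("u%03d", 1:150)
    direct <- lapply(universe_acc,
                     function(a) ids[runif(length(ids)) < 0.08])
    names(direct) <- universe_acc
    vp <- as_proteome(protein_table(universe_acc,
                                    rep("G", length(universe_acc)),
                                    go_terms = direct))
    study <- sample(universe_acc, 40)
    rows <- enrich(study, vp, dag)
    hits <- hits + sum(rows$p < 0.05)
    total <- total + nrow(rows)
  }
  frac <- hits / total
  # Fisher is conservative at small counts: the rejection rate must not
  # exceed alpha by more than binomial noise, and should not collapse to 0
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
  expect_gt(frac, 0.001)
})
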