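# Cohorts below are built so each member's HI-gene Jaccard with the index is
# exact by construction (see helper-fixtures.R).

test_that("connect applies the DE gate and the HI-similarity threshold", {
  # index shares DE gene g1 with M1-M3; D1 has a different DE set but
  # identical HI genes; U1 is a comparable patient with no DE gene
  sets <- list(
    IDX = 1:10,
    M1 = 1:10,                 # hi 1.0
    M2 = c(1:9, 11),           # hi 9/11
    M3 = c(1:7, 11:13),        # hi 7/13
    D1 = c(1:10, 20),          # contains second DE gene g20 -> discordant
    U1 = 2:10                  # lacks g1 -> DE-discordant with index
  )
  fix <- make_set_cohort(sets, n_genes = 20, de = c(1, 20))
  ann <- annotate_cohort(fix$cohort, fix$genes, "6")

  # threshold 0: all comparable DE-concordant patients
  expect_setequal(connect(ann, "IDX", 0), c("M1", "M2", "M3"))
  # identity passes any threshold
  expect_setequal(connect(ann, "IDX", 1), "M1")
  # DE discordance is a hard gate even at HI similarity 1.0
  cp <- compare_patients(ann, "IDX", "D1")
  expect_gt(cp$hi_gene_similarity, 0.9)
  expect_false("D1" %in% connect(ann, "IDX", 0))
  # threshold applied with tolerance: 9/11 passes 9/11 exactly
  expect_true("M2" %in% connect(ann, "IDX", 9 / 11))
  expect_false("M3" %in% connect(ann, "IDX", 9 / 11))
})

test_that("group size is non-increasing in the HI-similarity threshold", {
  set.seed(47)
  for (rep in 1:5) {
    sets <- random_sets(20, 10)
    fix <- make_set_cohort(sets, n_genes = 10, de = 1)
    ann <- annotate_cohort(fix$cohort, fix$genes, "6")
    grid <- seq(0, 1, by = 0.1)
    for (id in names(sets)) {
      sizes <- vapply(grid, function(t) length(connect(ann, id, t)),
                      numeric(1))
      expect_true(all(diff(sizes) <= 0))
    }
  }
})

test_that("connect is independent of cohort ordering", {
  set.seed(53)
  sets <- random_sets(15, 8)
  fix1 <- make_set_cohort(sets, n_genes = 8, de = 2)
  fix2 <- make_set_cohort(rev(sets), n_genes = 8, de = 2)
  ann1 <- annotate_cohort(fix1$cohort, fix1$genes, "6")
  ann2 <- annotate_cohort(fix2$cohort, fix2$genes, "6")
  for (id in names(sets)) {
    expect_identical(connect(ann1, id, 0.5), connect(ann2, id, 0.5))
    g1 <- select_tier(ann1, id)
    g2 <- select_tier(ann2, id)
    expect_identical(g1$members, g2$members)
    expect_identical(g1$tier_rule_applied, g2$tier_rule_applied)
  }
})

# Members at a prescribed HI-gene Jaccard with index {1..10}:
# shared genes 1..s plus (12 - s) private genes drawn from a block unique to
# the member gives jaccard s / (22 - 2s) ... constructed per case below.
member_sets <- function(n, shared, extra_per, first_free = 30) {
  out <- list()
  free <- first_free
  for (i in seq_len(n)) {
    out[[sprintf("M%02d", i)]] <- c(shared, seq(free, free + extra_per - 1))
    free <- free + extra_per
  }
  out
}

test_that("the highest qualifying tier is selected", {
  # 25 identical patients -> tier 1.0 (>= 20 rule) chosen first
  sets <- c(list(IDX = 1:10),
            stats::setNames(rep(list(1:10), 25), sprintf("M%02d", 1:25)))
  fix <- make_set_cohort(sets, n_genes = 10)
  ann <- annotate_cohort(fix$cohort, fix$genes, "6")
  g <- select_tier(ann, "IDX")
  expect_equal(g$hi_threshold_used, 1.0)
  expect_equal(length(g$members), 25)
  expect_match(g$tier_rule_applied, "hi>=1.0")
})

test_that("the >=15 rule at 0.7 catches groups too small at 0.8", {
  # 12 members at jaccard 9/11 (~0.818) and 4 more at 9/12 (0.75):
  # 12 < 20 at the 0.8 tier, 16 >= 15 at the 0.7 tier
  hi_members <- member_sets(12, 1:9, 2, first_free = 30)   # 9/13 ... no
  # shared 9, 2 extra -> |idx u m| = 10 + 2 = 13? idx has gene 10 private.
  # jaccard = 9 / (1 + 9 + 2) = 0.75 -- compute exactly instead:
  hi_members <- member_sets(12, 1:9, 1, first_free = 30)   # 9/(1+9+1) = 9/11
  mid_members <- member_sets(4, 1:9, 2, first_free = 60)   # 9/12 = 0.75
  names(mid_members) <- sprintf("N%02d", 1:4)
  sets <- c(list(IDX = 1:10), hi_members, mid_members)
  fix <- make_set_cohort(sets, n_genes = 70)
  ann <- annotate_cohort(fix$cohort, fix$genes, "6")

  expect_length(connect(ann, "IDX", 0.8), 12)
  expect_length(connect(ann, "IDX", 0.7), 16)
  g <- select_tier(ann, "IDX")
  expect_equal(g$hi_threshold_used, 0.7)
  expect_match(g$tier_rule_applied, "hi>=0.7,n>=15")
  expect_length(g$members, 16)
})

test_that("without a DE gene, too-small groups yield no description", {
  # 10 members at jaccard 1.0 -- below every size rule, no DE fallback
  sets <- c(list(IDX = 1:10), stats::setNames(rep(list(1:10), 10),
                                              sprintf("M%02d", 1:10)))
  fix <- make_set_cohort(sets, n_genes = 10)
  ann <- annotate_cohort(fix$cohort, fix$genes, "6")
  g <- select_tier(ann, "IDX")
  expect_equal(g$tier_rule_applied, "none")
  expect_length(g$members, 0)
  expect_true(is.na(g$hi_threshold_used))
})

test_that("a DE-gene index falls back to the highest threshold with >= 15", {
  # 17 members share DE gene g1 and sit at jaccard 8/14 (~0.571): empty
  # groups at every ruled tier (>= 0.6), 17 members from 0.5 down
  members <- member_sets(17, 1:8, 4, first_free = 30)
  sets <- c(list(IDX = 1:10), members)
  fix <- make_set_cohort(sets, n_genes = 120, de = 1)
  ann <- annotate_cohort(fix$cohort, fix$genes, "6")

  # verify the construction by enumerating connect() over the whole grid
  sizes <- vapply(seq(1, 0, by = -0.1),
                  function(t) length(connect(ann, "IDX", t)), numeric(1))
  expect_equal(sizes, c(0, 0, 0, 0, 0, 17, 17, 17, 17, 17, 17))

  g <- select_tier(ann, "IDX")
  expect_equal(g$hi_threshold_used, 0.5)
  expect_match(g$tier_rule_applied, "de_fallback")
  expect_length(g$members, 17)

  # the same cohort without the DE flag gets nothing
  fix2 <- make_set_cohort(sets, n_genes = 120)
  ann2 <- annotate_cohort(fix2$cohort, fix2$genes, "6")
  expect_equal(select_tier(ann2, "IDX")$tier_rule_applied, "none")
})

test_that("the selected tier satisfies its rule and no higher ruled tier does", {
  set.seed(59)
  settings <- similarity_settings(
    tier_rules = data.frame(min_hi = c(1, 0.8, 0.6), min_size = c(6L, 4L, 3L)),
    de_fallback_min_group = 3L)
  for (rep in 1:8) {
    sets <- random_sets(14, 8)
    fix <- make_set_cohort(sets, n_genes = 8, de = 1)
    ann <- annotate_cohort(fix$cohort, fix$genes, "6")
    for (id in names(sets)) {
      g <- select_tier(ann, id, settings)
      if (g$tier_rule_applied == "none") {
        # no ruled tier qualifies, and any fallback level is too small
        for (k in seq_len(nrow(settings$tier_rules))) {
          expect_lt(length(connect(ann, id, settings$tier_rules$min_hi[k],
                                   settings)),
                    settings$tier_rules$min_size[k])
        }
      } else if (grepl("de_fallback", g$tier_rule_applied)) {
        expect_gte(length(g$members), settings$de_fallback_min_group)
      } else {
        k <- which(abs(settings$tier_rules$min_hi - g$hi_threshold_used) < 1e-9)
        expect_gte(length(g$members), settings$tier_rules$min_size[k])
        if (k > 1) {
          for (j in seq_len(k - 1)) {
            expect_lt(length(connect(ann, id, settings$tier_rules$min_hi[j],
                                     settings)),
                      settings$tier_rules$min_size[j])
          }
        }
      }
    }
  }
})
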