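test_that("fsignal follows its definition in both orientations", {
  chars <- toy_chars()
  zero <- profile_of(E1 = 0, E2 = 0, E3 = 0)
  expect_equal(fsignal(zero, chars), 0)
  expect_equal(fsignal(zero, chars,
                       config = analysis_config(fsignal_orientation = "raw")),
               0)

  # one hyperactive effector driven to -0.8 reads +0.8 disease-oriented
  one <- disease_characterization(data.frame(protein = "E1", motive = 1,
                                             disease_sign = 1))
  p <- profile_of(E1 = -0.8)
  expect_equal(fsignal(p, one), 0.8)
  expect_equal(fsignal(p, one,
                       config = analysis_config(fsignal_orientation = "raw")),
               -0.8)

  # brute-force recomputation over the packaged mechanism table
  tbl <- read_mechanism_table(moanet_fixture("complementary"))
  rep_ <- mechanism_table_profiles(tbl)
  asn <- rep_$chars$assignments
  acts <- rep_$ab$activity[asn$protein]
  expect_equal(fsignal(rep_$ab, rep_$chars),
               mean(-asn$disease_sign * acts))
  m1 <- asn$motive == 1
  expect_equal(fsignal(rep_$ab, rep_$chars, motive = 1),
               mean(-asn$disease_sign[m1] * acts[m1]))
  expect_error(fsignal(rep_$ab, rep_$chars, motive = 99), "unknown")
})

test_that("reversion respects the inclusive 0.1 boundary", {
  chars <- disease_characterization(data.frame(
    protein = c("P1", "P2"), motive = 1, disease_sign = c(-1, 1)))
  # +0.1 against disease -1: exactly at threshold, included
  r1 <- reverted_effectors(profile_of(P1 = 0.1, P2 = 0), chars)
  expect_identical(r1$protein, "P1")
  # -0.09 against disease +1: below threshold, excluded
  r2 <- reverted_effectors(profile_of(P1 = 0, P2 = -0.09), chars)
  expect_identical(nrow(r2), 0L)
})

test_that("reverted sets shrink monotonically as the threshold grows", {
  set.seed(31)
  chars <- disease_characterization(data.frame(
    protein = paste0("P", 1:20), motive = rep(1:2, 10),
    disease_sign = sample(c(-1, 1), 20, replace = TRUE)))
  prof <- activity_profile(setNames(runif(20, -1, 1), paste0("P", 1:20)))
  thresholds <- c(0.05, 0.1, 0.3, 0.6)
  sets <- lapply(thresholds, function(t) {
    r <- reverted_effectors(prof, chars, analysis_config(t))
    paste(r$protein, r$motive)
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("percent_reversed counts unique proteins over unique effectors", {
  chars <- toy_chars()   # 3 unique proteins, E2 in two motives
  # E2 reverted in both motives must count once
  prof <- profile_of(E1 = 0, E2 = 0.5, E3 = 0)
  # E2 disease signs: -1 (M1) and +1 (M2); +0.5 reverts only the M1 pair
  expect_equal(percent_reversed(prof, chars), 100 * 1 / 3)
  expect_equal(percent_reversed(prof, chars, motive = 1), 50)
  all_rev <- profile_of(E1 = -0.5, E2 = 0.5, E3 = -0.5)
  expect_equal(percent_reversed(all_rev, chars, motive = 1), 100)
  expect_equal(percent_reversed(profile_of(E1 = 0, E2 = 0, E3 = 0), chars), 0)
})

test_that("the packaged tables replay to the published counts", {
  rt <- replay_tables()
  expect_true(all(rt$pass),
              info = paste(rt$check[!rt$pass], rt$mismatch[!rt$pass],
                           collapse = "; "))
  cmp <- attr(rt, "comparison")
  # single-drug reversion counts behind the decomposition
  expect_identical(length(unique(cmp$reverted_a$protein)), 23L)  # 13 + 10
  expect_identical(length(unique(cmp$reverted_b$protein)), 21L)  # 11 + 10
  expect_length(cmp$emergent, 0L)
  expect_length(cmp$attenuated, 0L)
})

test_that("a flipped fixture symbol is caught and named", {
  tbl <- read_mechanism_table(moanet_fixture("complementary"))
  tbl$mod_a[tbl$protein == "ITGA4"] <- 0L   # mutate: VDZ no longer reverts
  rep_ <- mechanism_table_profiles(rbind(
    tbl, read_mechanism_table(moanet_fixture("convergent"))))
  cmp <- compare_combination(rep_$a, rep_$b, rep_$ab, rep_$chars)
  expect_identical(length(cmp$exclusive_a), 12L)
  expect_false("ITGA4" %in% cmp$exclusive_a)
  expect_true("ITGA4" %in% cmp$emergent)
})

test_that("identical single-drug profiles leave no exclusive mechanisms", {
  chars <- disease_characterization(data.frame(
    protein = c("P1", "P2"), motive = 1, disease_sign = c(1, 1)))
  p <- profile_of(P1 = -0.5, P2 = -0.3)
  cmp <- compare_combination(p, p, p, chars)
  expect_length(cmp$exclusive_a, 0L)
  expect_length(cmp$exclusive_b, 0L)
  expect_setequal(cmp$convergent, c("P1", "P2"))
})

test_that("decomposition sets are disjoint and partition the reverted", {
  set.seed(17)
  for (rep in 1:5) {
    prot <- paste0("P", 1:15)
    chars <- disease_characterization(data.frame(
      protein = prot, motive = rep_len(1:3, 15),
      disease_sign = sample(c(-1, 1), 15, replace = TRUE)))
    mk <- function() activity_profile(setNames(runif(15, -1, 1), prot))
    cmp <- compare_combination(mk(), mk(), ab <- mk(), chars)
    sets <- list(cmp$convergent, cmp$exclusive_a, cmp$exclusive_b,
                 cmp$emergent, cmp$attenuated)
    pooled <- unlist(sets)
    expect_identical(anyDuplicated(pooled), 0L)
    expect_setequal(pooled, unique(cmp$reverted_ab$protein))
  }
})

test_that("combination magnitude rule separates convergent from attenuated", {
  chars <- disease_characterization(data.frame(
    protein = "P1", motive = 1, disease_sign = 1))
  a <- profile_of(P1 = -0.6); b <- profile_of(P1 = -0.4)
  strong <- compare_combination(a, b, profile_of(P1 = -0.6), chars)
  expect_identical(strong$convergent, "P1")
  weak <- compare_combination(a, b, profile_of(P1 = -0.5), chars)
  expect_identical(weak$attenuated, "P1")
  expect_length(weak$convergent, 0L)
})

test_that("bioflag corroboration classifies sign, threshold and absence", {
  bf <- bioflag_set(c("X", "Y", "Z", "W"), c(-1, -1, 1, 1))
  prof <- profile_of(X = -0.4, Y = 0.4, Z = 0.05)   # W absent
  rep_ <- corroborate_bioflags(prof, bf)
  expect_identical(rep_$n_evaluated, 3L)
  expect_identical(rep_$n_corroborated, 1L)
  expect_identical(rep_$n_antagonised, 1L)
  expect_identical(rep_$n_below_threshold, 1L)
  expect_identical(rep_$n_absent, 1L)
  st <- setNames(rep_$per_protein$status, rep_$per_protein$protein)
  expect_identical(st[["Y"]], "antagonised")
  expect_identical(st[["W"]], "absent")
  # all-zero profile: everything present is below threshold
  rep0 <- corroborate_bioflags(profile_of(X = 0, Y = 0, Z = 0, W = 0), bf)
  expect_identical(rep0$n_below_threshold, 4L)
  # counts always sum to evaluated
  expect_identical(rep_$n_corroborated + rep_$n_antagonised +
                     rep_$n_below_threshold, rep_$n_evaluated)
})

test_that("mechanism subnetwork keeps the stimulus-to-effector paths", {
  # T -> X -> E, plus a bystander branch that is not on any path
  net <- interaction_network(data.frame(
    source = c("T", "X", "B"), target = c("X", "E", "E")))
  sol <- model_solution(net, c(0.9, 0.9, 0.9), accuracy = 1)
  ens <- model_ensemble(list(sol), 0.9)
  chars <- disease_characterization(data.frame(
    protein = "E", motive = 1, disease_sign = 1))
  sub <- extract_moa_subnetwork(net, ens, c(T = -1), chars)
  expect_setequal(sub$nodes$protein, c("T", "X", "E"))
  expect_identical(sub$nodes$role[sub$nodes$protein == "T"], "target")
  expect_identical(sub$nodes$role[sub$nodes$protein == "E"], "effector")
  # edge signs: positive weight carrying negative activity = inhibition
  expect_true(all(sub$edges$sign == -1))

  # effector not reverted -> empty subgraph with a warning
  chars_neg <- disease_characterization(data.frame(
    protein = "E", motive = 1, disease_sign = -1))
  expect_warning(sub2 <- extract_moa_subnetwork(net, ens, c(T = -1),
                                                chars_neg),
                 "empty")
  expect_identical(nrow(sub2$nodes), 0L)
})

test_that("DOT export is well-formed and styled by role", {
  net <- interaction_network(data.frame(source = c("T", "X"),
                                        target = c("X", "E")))
  sol <- model_solution(net, c(0.9, 0.9), accuracy = 1)
  ens <- model_ensemble(list(sol), 0.9)
  chars <- disease_characterization(data.frame(
    protein = "E", motive = 1, disease_sign = 1))
  sub <- extract_moa_subnetwork(net, ens, c(T = -1), chars,
                                convergent = "E")
  path <- withr::local_tempfile(fileext = ".dot")
  write_dot(sub, path)
  dot <- readLines(path)
  expect_identical(dot[1], "digraph moa {")
  expect_identical(dot[length(dot)], "}")
  # balanced braces, every edge line colored
  expect_identical(sum(grepl("\\{", dot)), sum(grepl("\\}", dot)))
  expect_true(any(grepl("\"T\" \\[shape=diamond", dot)))
  expect_true(any(grepl("\"E\" \\[shape=circle, style=filled", dot)))
  expect_true(all(grepl("color=(red|green|grey)",
                        grep("->", dot, value = TRUE))))
})
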