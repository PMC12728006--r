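test_that("sign parsing covers both alphabets and rejects garbage", {
  expect_identical(parse_sign(c("up", "down", "+1", "-1")),
                   c(1L, -1L, 1L, -1L))
  expect_identical(parse_sign("none", allow_zero = TRUE), 0L)
  expect_error(parse_sign("none"), "not allowed")
  expect_error(parse_sign("sideways"), "unparseable")
  expect_error(parse_sign(0), "not allowed")
})

test_that("symbol normalization resolves hyphens, case and aliases", {
  expect_identical(normalize_symbol("MAdCAM-1"), "MADCAM1")
  expect_identical(normalize_symbol(c("nfkb2", " IL6 ")), c("NFKB2", "IL6"))
})

test_that("characterization validates assignments and counts uniques", {
  chars <- toy_chars()
  expect_identical(unique_effector_count(chars), 3L)
  expect_identical(nrow(chars$assignments), 4L)

  # duplicate (protein, motive) pair rejected
  expect_error(disease_characterization(data.frame(
    protein = c("A", "B", "A"), motive = c(1, 1, 1),
    disease_sign = c(1, 1, -1))), "duplicate")
  # bad sign rejected
  expect_error(disease_characterization(data.frame(
    protein = "A", motive = 1, disease_sign = 0)), "\\+1 or -1")
  # empty characterization is allowed and has zero effectors
  expect_identical(unique_effector_count(disease_characterization(NULL)), 0L)
})

test_that("unique count is bounded by the sum of motive sizes", {
  chars <- toy_chars()
  per_motive <- table(chars$assignments$motive)
  expect_lte(unique_effector_count(chars), sum(per_motive))
  # disjoint motives give equality
  disj <- disease_characterization(data.frame(
    protein = c("A", "B", "C"), motive = c(1, 1, 2),
    disease_sign = c(1, 1, 1)))
  expect_identical(unique_effector_count(disj), 3L)
})

test_that("characterization TSV and JSON round-trip field by field", {
  chars <- toy_chars()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_characterization(chars, tsv)
  write_characterization(chars, jsn)
  for (path in c(tsv, jsn)) {
    back <- read_characterization(path)
    expect_equal(back$assignments, chars$assignments)
    expect_equal(back$motives$motive, chars$motives$motive)
  }
})

test_that("empty characterization file loads as zero effectors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing here", path)
  expect_identical(unique_effector_count(read_characterization(path)), 0L)
})

test_that("packaged drug profiles carry the published targets", {
  vdz <- read_drug_profile(moanet_fixture("vdz_profile"), name = "VDZ")
  expect_setequal(names(vdz$targets), c("ITGA4", "ITGB7"))
  expect_identical(vdz$pseudotargets, c(MADCAM1 = -1L))
  expect_true(all(vdz$targets == -1))

  jaki <- read_drug_profile(moanet_fixture("jaki_profile"), name = "JAKi")
  expect_setequal(names(jaki$targets), c("JAK1", "JAK2", "JAK3", "TYK2"))
  expect_length(jaki$pseudotargets, 0)
  expect_true(all(jaki$targets == -1))
})

test_that("drug profile validation rejects empty and ill-signed inputs", {
  expect_error(drug_profile("x", numeric()), "at least one target")
  expect_error(drug_profile("x", c(A = 0)), "\\+1 or -1")
  expect_error(drug_profile("x", c(A = 1), pseudotargets = c(A = -1)),
               "disjoint")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein\teffect_sign\tis_pseudotarget",
               "GENE1\t0\tFALSE"), path)
  expect_error(read_drug_profile(path), "not allowed")
})

test_that("drug profile round-trips through TSV and JSON", {
  prof <- drug_profile("combo", c(A = -1, B = 1), c(C = -1))
  for (ext in c(".tsv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_drug_profile(prof, path)
    back <- read_drug_profile(path, name = "combo")
    expect_equal(back$targets, prof$targets)
    expect_equal(back$pseudotargets, prof$pseudotargets)
  }
})

test_that("mechanism-table fixtures match the published row sets", {
  comp <- read_mechanism_table(moanet_fixture("complementary"))
  expect_identical(nrow(comp), 24L)
  expect_identical(comp$protein[1], "ITGA4")
  expect_identical(comp$protein[24], "CLDN3")
  expect_setequal(unique(unlist(comp$motives)), c(1L, 3L, 4L))

  conv <- read_mechanism_table(moanet_fixture("convergent"))
  expect_setequal(conv$protein,
                  c("TCF4", "IFNG", "FASLG", "CCR9", "MMP1", "CDH1",
                    "NFKB1", "PLA2G1B", "MAPK3", "MAPK1"))

  # per-row motive and sign lists stay aligned
  expect_true(all(lengths(comp$motives) == lengths(comp$disease_signs)))
})

test_that("bioflag table fixture parses with its published statuses", {
  bft <- read_bioflag_table(moanet_fixture("vdz_bioflags"))
  expect_identical(nrow(bft), 22L)
  expect_true(all(bft$bioflag_sign == -1L))
  expect_identical(sum(bft$status_combo == "blank"), 1L)
  expect_identical(bft$protein[bft$status_combo == "antagonised"], "TLR6")
})

test_that("published-scale synthetic characterization hits 148 unique effectors", {
  sys <- generate_system(synthetic_spec(
    n_nodes = 900, mean_degree = 4, motive_sizes = c(50L, 24L, 45L, 59L),
    n_unique_effectors = 148L, n_rules = 5L, seed = 11))
  # independent recount: direct set union over assignment rows
  expect_identical(length(unique(sys$chars$assignments$protein)), 148L)
  expect_identical(unique_effector_count(sys$chars), 148L)
  sizes <- table(sys$chars$assignments$motive)
  expect_identical(as.integer(sizes), c(50L, 24L, 45L, 59L))
})
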