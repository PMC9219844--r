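test_that("EC syntax validation accepts four-field codes and partial codes", {
  expect_true(all(is_ec(c("1.3.1.24", "2.4.2.8", "1.3.1.243", "1.3.1.-"))))
  expect_false(any(is_ec(c("1.3.1", "a.b.c.d", "1.3.1.24.5", ""))))
})

test_that("transcript ECs honor significance and confidence tier", {
  maps <- toy_maps()
  degs <- data.frame(gene = c("g1", "g2", "g3"),
                     q_value = c(0.01, 0.01, 0.2))
  # g1 (gold PF00001 -> two ECs) and g2 (silver PF00002) significant;
  # g3 not significant
  expect_equal(ecs_from_degs(degs, maps, tier = "gold"),
               c("1.1.1.1", "2.2.2.2"))
  expect_equal(ecs_from_degs(degs, maps, tier = "silver"),
               c("1.1.1.1", "2.2.2.2", "3.3.3.3"))
  # silver-only association vanishes at gold tier
  degs2 <- data.frame(gene = "g2", q_value = 0.001)
  expect_equal(ecs_from_degs(degs2, maps, tier = "gold"), character(0))
  # gene without a PFAM is skipped with a message
  degs3 <- data.frame(gene = c("g1", "orphan"), q_value = c(0.01, 0.01))
  expect_message(ecs_from_degs(degs3, maps), "without a PFAM")
})

test_that("metabolite ECs come from rank-1 annotations via CAS then name", {
  maps <- toy_maps()
  ann <- data.frame(
    id = c("f1", "f2", "f3", "f4"),
    compound = c("hypoxanthine", "cpdX", NA, "hypoxanthine"),
    compound_cas = c("68-94-0", "", NA, "68-94-0"),
    p_value = c(1e-5, 1e-5, 1e-6, 0.5))
  expect_message(
    ecs <- ecs_from_metabolites(ann, maps, p_threshold = 0.001),
    "unannotated")
  expect_equal(ecs, c("1.17.1.4", "2.2.2.2"))
  # nothing significant -> empty set
  expect_equal(ecs_from_metabolites(ann, maps, p_threshold = 1e-9),
               character(0))
})

test_that("EC overlap is an exact intersection ignoring partial codes", {
  a <- c("1.1.1.1", "2.2.2.2", "3.3.3.3", "9.9.9.-")
  b <- c("2.2.2.2", "3.3.3.3", "4.4.4.4", "9.9.9.-")
  ov <- overlap_ecs(a, b)
  expect_equal(ov, c("2.2.2.2", "3.3.3.3"))
  expect_true(all(ov %in% a) && all(ov %in% b))
  expect_equal(overlap_ecs(c("1.1.1.1"), c("2.2.2.2")), character(0))
  expect_equal(overlap_ecs(a, a), sort(setdiff(a, "9.9.9.-")))
  expect_lte(length(ov), min(length(a), length(b)))
})

test_that("reaction expansion deduplicates and classifies evidence", {
  maps <- toy_maps()
  # 1.1.1.1 -> {R1, R2}; 2.2.2.2 -> {R2}: 3 pairs, 2 distinct reactions
  recs <- reactions_for_ecs(c("1.1.1.1", "2.2.2.2"), maps,
                            transcript_ecs = c("1.1.1.1", "2.2.2.2"),
                            metabolite_ecs = c("1.1.1.1", "2.2.2.2"))
  expect_equal(recs$reaction, c("R1", "R2"))
  expect_true(all(recs$evidence == "both"))
  expect_false(any(duplicated(recs$reaction)))

  recs2 <- reactions_for_ecs(c("1.1.1.1", "1.17.1.4"), maps,
                             transcript_ecs = "1.1.1.1",
                             metabolite_ecs = "1.17.1.4")
  expect_equal(recs2$evidence[recs2$reaction == "R1"], "transcript_only")
  expect_equal(recs2$evidence[recs2$reaction == "R3"], "metabolite_only")
  expect_equal(recs2$pathways[recs2$reaction == "R3"], "pwB")

  expect_message(
    reactions_for_ecs(c("1.1.1.1", "8.8.8.8"), maps, "1.1.1.1", character(0)),
    "absent from the reaction table")
})

test_that("iPath export encodes evidence as color and width", {
  maps <- toy_maps()
  recs <- reactions_for_ecs(c("1.1.1.1", "2.2.2.2", "1.17.1.4"), maps,
                            transcript_ecs = c("1.1.1.1", "2.2.2.2"),
                            metabolite_ecs = c("1.1.1.1", "1.17.1.4"))
  path <- tempfile()
  export_ipath(recs, path)
  lines <- readLines(path)
  expect_equal(lines[1], "1.1.1.1 #000000 W20")
  expect_true("1.17.1.4 #0000ff W10" %in% lines)
  expect_true("2.2.2.2 #00ff00 W10" %in% lines)
  expect_equal(lines, sort(lines))
  expect_error(export_ipath(recs[0, ], tempfile()), "no reaction")
})

test_that("called overlap matches planted truth under perfect recovery", {
  ds <- small_sim(seed = 30)
  # feed the truth sets straight through the integration surface
  called <- overlap_ecs(ds$truth$transcript_ecs, ds$truth$metabolite_ecs)
  expect_equal(called, ds$truth$overlap_ecs)
  expect_true(length(ds$truth$overlap_ecs) >= 1)
})
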