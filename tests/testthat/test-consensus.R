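residues4 <- data.frame(chain = "A", res_id = c(363, 273, 280, 270),
                        res_name = c("HIS", "PHE", "TYR", "ILE"))

test_that("occurrence counting uses distinct ligands and stable annotations", {
  tab <- data.frame(
    ligand_id = c("L1", "L1", "L2", "L3"),
    chain = "A", res_id = c(363, 363, 363, 280),
    res_name = c("HIS", "HIS", "HIS", "TYR"),
    interaction_class = c("hbond", "pi", "vdw", "hbond"))
  cnt <- occurrence_counts(tab, n_ligands = 15)
  # two classes for ligand L1 count once
  expect_equal(cnt$count[cnt$residue == "His363"], 2)
  expect_equal(cnt$count[cnt$residue == "Tyr280"], 1)
  expect_equal(cnt$annotation[cnt$residue == "His363"], "His363 (2)")
  # invariant to row order and duplicated rows
  tab2 <- rbind(tab[c(4, 3, 2, 1), ], tab[2, ])
  cnt2 <- occurrence_counts(tab2, n_ligands = 15)
  expect_equal(cnt2[order(cnt2$residue), c("residue", "count")],
               cnt[order(cnt$residue), c("residue", "count")],
               ignore_attr = TRUE)
})

test_that("the half-the-ligands filter keeps 7/15 and drops 6/15", {
  spec <- table_spec(15, residues4, occurrence = c(13, 7, 6, 8), seed = 2)
  cnt <- occurrence_counts(make_interaction_table(spec), n_ligands = 15)
  kept <- filter_by_occurrence(cnt, 15)
  expect_true(all(c("His363", "Phe273", "Ile270") %in% kept))
  expect_false("Tyr280" %in% kept)  # 6 of 15 is below floor(15/2) = 7
  # boundary at even n: 5 of 10 is kept
  spec10 <- table_spec(10, residues4, occurrence = c(5, 4, 0, 0), seed = 3)
  kept10 <- filter_by_occurrence(occurrence_counts(make_interaction_table(spec10),
                                                   n_ligands = 10), 10)
  expect_true("His363" %in% kept10)
  expect_false("Phe273" %in% kept10)
  expect_error(filter_by_occurrence(cnt, 0), "positive")
})

test_that("occupancy and energy evidence sets apply their cutoffs", {
  occ <- data.frame(donor_res = c("His363", "Phe70", "Gln140"),
                    acceptor_res = c("Lig1", "Lig1", "Lig1"),
                    pct = c(46.25, 2.20, 1.9))
  s <- occupancy_set(occ, min_pct = 2.0, ligand_res = "Lig1")
  expect_true(all(c("His363", "Phe70") %in% s))
  expect_false("Gln140" %in% s)  # 1.9% falls below the 2.0 cutoff
  expect_equal(occupancy_set(occ[0, ]), character(0))

  et <- data.frame(complex_id = "c", chain = "A", res_id = c(1, 2, 3),
                   res_name = c("ALA", "VAL", "LEU"),
                   energy_kcal_mol = c(-3.0, -1.2, -0.4))
  expect_equal(sort(energy_set(et, max_energy = -1.0)), c("Ala1", "Val2"))
  expect_equal(energy_set(et, top_k = 1), "Ala1")
  expect_error(energy_set(et, max_energy = -1, top_k = 2), "not both")
  expect_equal(energy_set(et[0, ]), character(0))
})

test_that("consensus scoring ranks evidence count then dynamics priority", {
  rep <- hotspot_consensus(
    occurrence_set = c("His363", "Phe273", "Tyr280"),
    occupancy_set = c("His363", "Phe273", "Gln345"),
    energy_set = c("His363", "Gln345"),
    occupancy_pct = c(His363 = 46, Phe273 = 10, Gln345 = 5))
  expect_equal(rep$residue[1], "His363")
  expect_equal(rep$evidence_score[1], 3)
  # among score-2 residues, occupancy+energy outranks occurrence+occupancy
  s2 <- rep[rep$evidence_score == 2, ]
  expect_equal(s2$residue[1], "Gln345")
  expect_equal(s2$residue[2], "Phe273")
  expect_warning(
    hotspot_consensus(c("Ala1"), c("Val2"), c("Leu3")), "disjoint")
})

test_that("adding evidence never lowers a residue's rank (monotonicity)", {
  base_rep <- hotspot_consensus(c("A1", "B2"), c("B2", "C3"), c("C3"))
  with_more <- hotspot_consensus(c("A1", "B2"), c("B2", "C3", "A1"), c("C3"))
  rank_of <- function(r, res) r$rank[r$residue == res]
  expect_lte(rank_of(with_more, "A1"), rank_of(base_rep, "A1"))
})

test_that("end-to-end planted hot spots are recovered exactly", {
  set.seed(99)
  for (k in 1:5) {
    ids <- sort(sample(50:400, 6))
    res <- data.frame(chain = "A", res_id = ids,
                      res_name = sample(c("HIS", "PHE", "TYR", "GLN", "VAL",
                                          "LEU"), 6, replace = TRUE))
    hot <- 1:3  # plant rows 1-3 as the hot spots on all three streams
    occ_cnt <- ifelse(seq_len(6) %in% hot, 10, 3)
    energy <- ifelse(seq_len(6) %in% hot, -2.5, -0.2)
    spec <- table_spec(15, res, occurrence = occ_cnt, energy = energy,
                       seed = k)
    labs <- residue_label(res$res_name, res$res_id)
    occ_pct <- setNames(ifelse(seq_len(6) %in% hot, 40, 0.5), labs)
    o_set <- filter_by_occurrence(
      occurrence_counts(make_interaction_table(spec), n_ligands = 15), 15)
    q_set <- names(occ_pct)[occ_pct >= 2]
    e_set <- energy_set(make_energy_table(spec), max_energy = -1)
    rep <- hotspot_consensus(o_set, q_set, e_set, occupancy_pct = occ_pct)
    expect_setequal(rep$residue[1:3], labs[hot])
    expect_true(all(rep$evidence_score[1:3] == 3))
  }
})
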