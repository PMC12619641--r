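# Exclusion-list removal, query-presence check and the 6 A pocket gate.

# protein chain A (5 CA) plus a ligand at a controlled distance from CA3,
# and an optional second chain Z close to the ligand.
pocket_cif <- function(lig_dist, with_far_chain = FALSE) {
  p <- tempfile(fileext = ".cif")
  atoms <- data.frame(record = "ATOM", name = "CA", element = "C",
                      comp = "ALA", chain = "A", seq = 1:5, entity = "1",
                      x = 3.8 * (1:5), y = 0, z = 0)
  lig <- data.frame(record = "HETATM", name = "C1", element = "C",
                    comp = "LIG", chain = "A", seq = 101L, entity = "2",
                    x = 3.8 * 3, y = lig_dist, z = 0)
  atoms <- rbind(atoms, lig)
  entities <- data.frame(id = c("1", "2"),
                         type = c("polymer", "non-polymer"),
                         src = c("man", "syn"))
  if (with_far_chain) {
    atoms <- rbind(atoms, data.frame(
      record = "ATOM", name = "CA", element = "C", comp = "GLY",
      chain = "Z", seq = 1:2, entity = "3",
      x = 3.8 * 3 + c(0, 3.8), y = lig_dist + 3, z = 0))
    entities <- rbind(entities, data.frame(id = "3", type = "polymer",
                                           src = "man"))
  }
  write_test_cif(p, "pkt1", atoms, entities,
                 refs = data.frame(db = "UNP", acc = "P0TEST1",
                                   entity = "1", chain = "A"))
  resolve_altlocs(parse_mmcif(p))
}

lig_candidate <- function(s) {
  res <- subset(
    data.frame(chain = s$atoms$auth_chain, seq = s$atoms$auth_seq,
               comp = s$atoms$comp_id),
    comp == "LIG")[1, ]
  list(ligand_uid = "LIG_A_101", label = "LIG", kind = "small_molecule",
       residues = data.frame(res_key = paste0(res$chain, "|", res$seq, "|"),
                             chain = res$chain, auth_seq = res$seq,
                             ins_code = NA_character_, comp_id = "LIG",
                             record_kind = "HETATM",
                             stringsAsFactors = FALSE),
       heavy_atom_count = 1L, covalent_to_protein = FALSE,
       prd_id = NA_character_, flags = character(0), chain = res$chain,
       entity_id = "2")
}

test_that("exclusion list removes single-residue matches but never multi-residue ligands", {
  cands <- list(
    lig_candidate(pocket_cif(3)),
    local({
      cn <- lig_candidate(pocket_cif(3))
      cn$residues <- rbind(cn$residues, transform(cn$residues,
                                                  res_key = "A|102|",
                                                  auth_seq = 102L,
                                                  comp_id = "GOL"))
      cn$residues$comp_id <- c("PHQ", "GOL")
      cn$label <- "PHQ-GOL"
      cn$ligand_uid <- "PHQ-GOL_A_101"
      cn
    })
  )
  cands[[1]]$residues$comp_id <- "BEN"
  cands[[1]]$label <- "BEN"
  out <- filter_exclusion_list(cands, c("BEN", "GOL"))
  expect_length(out$candidates, 1L)
  expect_equal(out$candidates[[1]]$label, "PHQ-GOL")
  expect_match(out$log, "BEN")
})

test_that("the query-presence check honors secondary accessions", {
  s <- pocket_cif(3)
  expect_true(require_query_chain(s, "P0TEST1"))
  expect_true(require_query_chain(s, "Q0OLD1",
                                  aliases = c(Q0OLD1 = "P0TEST1")))
  expect_false(require_query_chain(s, "P9XXXX9"))
})

test_that("the 6 A gate is boundary-inclusive and requires query-chain contact", {
  # 5.9 A from the query chain: kept, residue listed
  s_in <- pocket_cif(5.9)
  pg <- pocket_gate(list(lig_candidate(s_in)), s_in, "A")
  expect_length(pg$pockets, 1L)
  expect_true(pg$pockets[[1]]$query_contact)
  expect_true(all(pg$pockets[[1]]$nearby$chain == "A"))

  # 6.1 A from the query, 3 A from another chain: discarded and logged
  s_out <- pocket_cif(6.1, with_far_chain = TRUE)
  pg2 <- pocket_gate(list(lig_candidate(s_out)), s_out, "A")
  expect_length(pg2$pockets, 0L)
  expect_match(pg2$log, "NO_QUERY_CONTACT")

  # apo: no candidates in, none out
  expect_length(pocket_gate(list(), s_in, "A")$pockets, 0L)
})

test_that("pocket residues equal the brute-force all-pairs oracle", {
  bed <- fixture_bed()
  for (f in file.path(bed$cif_dir, c("s001.cif", "s005.cif", "s009.cif"))) {
    s <- resolve_altlocs(parse_mmcif(f))
    en <- enumerate_candidates(s, build_connectivity_graph(s),
                               empty_refs())
    pg <- pocket_gate(en$candidates, s, "A")
    for (p in pg$pockets) {
      oracle <- brute_force_pocket(s, p$residues$res_key, 6.0)
      # restrict the oracle to polymer residues, as the gate does
      res <- setdiff(oracle, p$residues$res_key)
      got <- paste(p$nearby$chain, p$nearby$auth_seq, "", sep = "|")
      poly <- grepl("^A\\|", res)
      expect_setequal(got, res[poly])
    }
  }
})

test_that("every surviving pocket record reports query contact and a true count", {
  bed <- fixture_bed()
  s <- resolve_altlocs(parse_mmcif(file.path(bed$cif_dir, "s005.cif")))
  en <- enumerate_candidates(s, build_connectivity_graph(s), empty_refs())
  pg <- pocket_gate(en$candidates, s, "A")
  expect_gt(length(pg$pockets), 0L)
  for (p in pg$pockets) {
    expect_true(p$query_contact)
    expect_equal(p$residue_count, nrow(p$nearby))
  }
})

test_that("gate output is independent of candidate order", {
  bed <- fixture_bed()
  s <- resolve_altlocs(parse_mmcif(file.path(bed$cif_dir, "s005.cif")))
  en <- enumerate_candidates(s, build_connectivity_graph(s), empty_refs())
  a <- pocket_gate(en$candidates, s, "A")
  b <- pocket_gate(rev(en$candidates), s, "A")
  uids <- function(pg) sort(vapply(pg$pockets,
                                   function(p) p$ligand_uid, ""))
  expect_equal(uids(a), uids(b))
})
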