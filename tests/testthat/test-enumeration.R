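# Connectivity graph, peptide/oligosaccharide classification, candidate
# assembly and enumeration-stage filters.

chain_cif <- function(n = 5L, record = "ATOM", conn = NULL,
                      comp = "ALA") {
  p <- tempfile(fileext = ".cif")
  atoms <- data.frame(record = record, name = "CA", element = "C",
                      comp = comp, chain = "A", seq = seq_len(n),
                      entity = "1", x = 3.8 * seq_len(n), y = 0, z = 0)
  write_test_cif(p, "chn1", atoms,
                 data.frame(id = "1", type = "polymer", src = "man"),
                 conn = conn)
  parse_mmcif(p)
}

test_that("consecutive ATOM residues are implicitly connected, HETATM are not", {
  g <- build_connectivity_graph(chain_cif(5L, "ATOM"))
  expect_equal(igraph::vcount(g), 5L)
  expect_equal(igraph::ecount(g), 4L)
  expect_equal(igraph::components(g)$no, 1L)

  g2 <- build_connectivity_graph(chain_cif(2L, "HETATM", comp = "LIG"))
  expect_equal(igraph::ecount(g2), 0L)
  expect_equal(igraph::components(g2)$no, 2L)
})

test_that("an intercalated ATOM/HETATM chain is rebuilt into one component", {
  sc <- generate_scenario("S4", tempfile())
  s <- resolve_altlocs(parse_mmcif(sc$files[1]))
  g <- build_connectivity_graph(s)
  memb <- igraph::components(g)$membership
  b_nodes <- grep("^B\\|", names(memb), value = TRUE)
  expect_length(b_nodes, 11L)
  expect_length(unique(memb[b_nodes]), 1L)
})

test_that("covale records referencing missing residues are skipped with a warning", {
  conn <- data.frame(type = "covale", chain1 = "A", seq1 = 1,
                     comp1 = "ALA", atom1 = "C", chain2 = "Z", seq2 = 99,
                     comp2 = "XXX", atom2 = "N")
  expect_warning(g <- build_connectivity_graph(chain_cif(3L, conn = conn)),
                 "skipped")
  expect_equal(igraph::ecount(g), 2L)
})

test_that("graph components agree with a union-find oracle on every scenario", {
  bed <- fixture_bed()
  for (f in list.files(bed$cif_dir, full.names = TRUE)) {
    s <- resolve_altlocs(parse_mmcif(f))
    g <- build_connectivity_graph(s)
    el <- igraph::as_edgelist(g)
    oracle <- uf_components(igraph::V(g)$name,
                            data.frame(a = el[, 1], b = el[, 2],
                                       stringsAsFactors = FALSE))
    memb <- igraph::components(g)$membership
    expect_equal(length(oracle), max(memb))
    for (grp in oracle) {
      expect_length(unique(memb[grp]), 1L)
    }
  }
})

test_that("protein-covalent links are reported with their atoms", {
  sc <- generate_scenario("S6", tempfile())
  s <- resolve_altlocs(parse_mmcif(sc$files[1]))
  links <- detect_protein_covalent_links(s)
  expect_equal(nrow(links), 1L)
  expect_equal(links$ligand_comp, "CVX")
  expect_equal(links$protein_comp, "LYS")
  expect_equal(links$ligand_atom, "C1")
  expect_equal(links$protein_atom, "NZ")
})

test_that("glycosylation attachment is a protein-covalent link; disulfides are not", {
  sc <- generate_scenario("S7", tempfile())
  s <- resolve_altlocs(parse_mmcif(sc$files[1]))
  links <- detect_protein_covalent_links(s)
  expect_true(any(links$ligand_comp == "NAG" &
                    links$protein_comp == "ASN"))

  conn <- data.frame(type = "disulf", chain1 = "A", seq1 = 1,
                     comp1 = "CYS", atom1 = "SG", chain2 = "A", seq2 = 3,
                     comp2 = "CYS", atom2 = "SG")
  s2 <- chain_cif(3L, comp = "CYS", conn = conn)
  expect_equal(nrow(detect_protein_covalent_links(s2)), 0L)
})

test_that("unmapped chains classify as peptide ligands, full-length proteins do not", {
  sc5 <- generate_scenario("S5", tempfile())
  s5 <- resolve_altlocs(parse_mmcif(sc5$files[1]))
  refs <- empty_refs()
  cls <- classify_chain_as_peptide_ligand("E", s5, refs)
  expect_true(cls$is_ligand)
  expect_equal(cls$reason, "unmapped-chain")

  sc11 <- generate_scenario("S11", tempfile())
  s11 <- resolve_altlocs(parse_mmcif(sc11$files[1]))
  refs11 <- empty_refs(uniprot_lengths = c(P0TEST2 = 36L))
  cls11 <- classify_chain_as_peptide_ligand("L", s11, refs11)
  expect_false(cls11$is_ligand)
  expect_equal(cls11$reason, "full-length-protein")
  expect_error(classify_chain_as_peptide_ligand("Z", s11, refs11), "Z")
})

test_that("a chain whose sequence matches the reference dictionary is confirmed", {
  sc4 <- generate_scenario("S4", tempfile())
  s4 <- resolve_altlocs(parse_mmcif(sc4$files[1]))
  refs <- empty_refs(bird = data.frame(prd_id = "PRD_000001",
                                       sequence = "AXAXAXAXAXA",
                                       stringsAsFactors = FALSE))
  cls <- classify_chain_as_peptide_ligand("B", s4, refs)
  expect_true(cls$is_ligand)
  expect_equal(cls$reason, "bird-match")
  expect_equal(cls$prd_id, "PRD_000001")
})

test_that("a covale-linked fragment pair is enumerated as one candidate", {
  sc <- generate_scenario("S3", tempfile())
  s <- resolve_altlocs(parse_mmcif(sc$files[1]))
  en <- enumerate_candidates(s, build_connectivity_graph(s), empty_refs())
  expect_length(en$candidates, 1L)
  cand <- en$candidates[[1]]
  expect_equal(nrow(cand$residues), 2L)
  expect_setequal(cand$residues$comp_id, c("PHQ", "DGL"))
  expect_true("reassembled_multi_residue" %in% cand$flags)
})

test_that("a peptide chain and a small molecule are both enumerated", {
  sc <- generate_scenario("S5", tempfile())
  s <- resolve_altlocs(parse_mmcif(sc$files[1]))
  en <- enumerate_candidates(s, build_connectivity_graph(s), empty_refs())
  kinds <- vapply(en$candidates, function(cn) cn$kind, "")
  labels <- vapply(en$candidates, function(cn) cn$label, "")
  expect_setequal(labels, c("ATP", "CHAIN-E"))
  expect_setequal(kinds, c("small_molecule", "chain_peptide"))
})

test_that("glycosylation-only structures yield no candidates", {
  sc <- generate_scenario("S7", tempfile())
  s <- resolve_altlocs(parse_mmcif(sc$files[1]))
  en <- enumerate_candidates(s, build_connectivity_graph(s), empty_refs())
  expect_length(en$candidates, 0L)
  expect_true(any(grepl("GLYCOSYLATION_EXCLUDED", en$log)))
})

test_that("oligosaccharide triage separates glycosylation, free chains and dictionary hits", {
  sc7 <- generate_scenario("S7", tempfile())
  s7 <- resolve_altlocs(parse_mmcif(sc7$files[1]))
  o7 <- classify_oligosaccharide("2", s7, empty_refs())
  expect_false(o7$is_ligand)
  expect_equal(o7$reason, "N-glycosylation")

  sc8 <- generate_scenario("S8", tempfile())
  s8 <- resolve_altlocs(parse_mmcif(sc8$files[1]))
  o8 <- classify_oligosaccharide("2", s8, empty_refs())
  expect_true(o8$is_ligand)
  expect_equal(o8$reason, "free-oligosaccharide")

  # dictionary-matched branch attached to protein: kept but flagged covalent
  refs_bird <- empty_refs(bird = data.frame(
    prd_id = "PRD_000900", sequence = "NAG-NAG-BMA",
    stringsAsFactors = FALSE))
  o7b <- classify_oligosaccharide("2", s7, refs_bird)
  expect_true(o7b$is_ligand)
  expect_true(o7b$covalent)
  expect_equal(o7b$prd_id, "PRD_000900")
})

test_that("no residue ever appears in two candidates", {
  bed <- fixture_bed()
  for (f in list.files(bed$cif_dir, full.names = TRUE)) {
    s <- resolve_altlocs(parse_mmcif(f))
    en <- enumerate_candidates(s, build_connectivity_graph(s),
                               empty_refs())
    keys <- unlist(lapply(en$candidates, function(cn) cn$residues$res_key))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("frequent codes are flagged unless kept; tiny and over-copied ligands are removed", {
  counts <- c(GOL = 10000L, ATP = 5000L, XYZ = 50L, O2 = 100L)
  cands <- list(make_cand("GOL"), make_cand("ATP"),
                make_cand("O2", heavy = 2L))
  out <- apply_enumeration_filters(cands, counts, keep = "ATP")
  labels <- vapply(out$candidates, function(cn) cn$label, "")
  expect_setequal(labels, c("GOL", "ATP"))
  flags <- lapply(out$candidates, function(cn) cn$flags)
  expect_true("frequent_ligand" %in%
                flags[[which(labels == "GOL")]])
  expect_false("frequent_ligand" %in%
                 flags[[which(labels == "ATP")]])
  expect_true(any(grepl("EXCLUDED_SIZE", out$log)))

  # 12 copies of one code in a single structure -> all removed
  many <- lapply(1:12, function(i) make_cand("XYZ", seq0 = 100L + i))
  out2 <- apply_enumeration_filters(c(many, list(make_cand("ATP"))),
                                    counts, keep = "ATP")
  expect_equal(vapply(out2$candidates, function(cn) cn$label, ""), "ATP")
  expect_true(any(grepl("EXCLUDED_COPIES", out2$log)))

  # no survivor under the minimum heavy-atom count
  expect_true(all(vapply(out$candidates,
                         function(cn) cn$heavy_atom_count, 0L) >= 3L))
})
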