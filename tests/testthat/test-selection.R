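# Subsumed-fragment removal, filter-mode deduplication, superposition and
# centroid clustering.

pocketize <- function(cand, count) {
  cand$residue_count <- count
  cand$nearby <- data.frame(chain = "A", auth_seq = seq_len(count),
                            comp_id = "ALA", stringsAsFactors = FALSE)
  cand$contact_chains <- "A"
  cand$query_contact <- TRUE
  cand
}

frag_graph <- function() {
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, 3,
                            name = c("A|301|", "A|302|", "A|400|"))
  igraph::add_edges(g, c("A|301|", "A|302|"), bond = "covale")
}

test_that("a fragment inside a larger reassembled ligand is removed", {
  small <- make_cand("PHQ", seq0 = 301L)
  big <- make_cand("PHQ", n_res = 2L, seq0 = 301L)
  big$residues$comp_id <- c("PHQ", "DGL")
  big$label <- "PHQ-DGL"
  big$ligand_uid <- "PHQ-DGL_A_301"
  out <- remove_subsumed_fragments(list(small, big), frag_graph())
  expect_length(out$pockets, 1L)
  expect_equal(out$pockets[[1]]$label, "PHQ-DGL")
  expect_match(out$log, "SUBSUMED")
})

test_that("a ligand bonded to an outside non-protein residue is removed as incomplete", {
  lone <- make_cand("MCM", seq0 = 301L)  # bonded to A|302| outside itself
  out <- remove_subsumed_fragments(list(lone), frag_graph())
  expect_length(out$pockets, 0L)
  expect_match(out$log, "INCOMPLETE")
  # but not when the neighbor is protein
  out2 <- remove_subsumed_fragments(list(lone), frag_graph(),
                                    protein_keys = "A|302|")
  expect_length(out2$pockets, 1L)
})

test_that("disjoint unconnected ligands are both kept", {
  a <- make_cand("AAA", seq0 = 301L)
  b <- make_cand("BBB", seq0 = 400L)
  out <- remove_subsumed_fragments(list(a, b), frag_graph(),
                                   protein_keys = "A|302|")
  expect_length(out$pockets, 2L)
})

test_that("deduplication keeps the copy with most nearby residues, ties lexicographic", {
  copies <- list(
    pocketize(make_cand("5U6", chain = "A", seq0 = 701L), 18L),
    pocketize(make_cand("5U6", chain = "B", seq0 = 701L), 22L),
    pocketize(make_cand("5U6", chain = "C", seq0 = 701L), 20L))
  sel <- deduplicate_filter_mode(copies)
  expect_length(sel, 1L)
  expect_equal(sel[[1]]$chain, "B")
  # coordinates/residues of the survivor are untouched
  expect_identical(sel[[1]]$residues, copies[[2]]$residues)

  tie <- list(pocketize(make_cand("PEP", chain = "D", seq0 = 1L,
                                  kind = "chain_peptide"), 15L),
              pocketize(make_cand("PEP", chain = "B", seq0 = 1L,
                                  kind = "chain_peptide"), 15L))
  tie[[1]]$entity_id <- tie[[2]]$entity_id <- "7"
  expect_equal(deduplicate_filter_mode(tie)[[1]]$chain, "B")

  single <- list(pocketize(make_cand("ONE"), 4L))
  expect_identical(deduplicate_filter_mode(single), single)
})

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

test_that("superposition is exact under rigid motion and matches the quaternion oracle", {
  set.seed(11)
  ref <- matrix(rnorm(30), 10, 3)
  mob <- ref %*% t(rot_z(30)) + matrix(rep(c(5, -2, 1), each = 10), 10, 3)
  sup <- kabsch_superpose(mob, ref)
  expect_lt(sup$rmsd, 1e-6)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-6)
  moved <- mob %*% t(sup$rotation) +
    matrix(rep(sup$translation, each = 10), 10, 3)
  expect_equal(moved, ref, tolerance = 1e-6, ignore_attr = TRUE)

  for (i in 1:100) {
    a <- matrix(rnorm(30, sd = 3), 10, 3)
    b <- matrix(rnorm(30, sd = 3), 10, 3)
    expect_lt(abs(kabsch_superpose(a, b)$rmsd - quaternion_rmsd(a, b)),
              1e-8)
  }
})

test_that("RMSD under isotropic jitter matches the closed-form expectation", {
  # per-coordinate sd 0.1 -> E[rmsd] ~= 0.1 * sqrt(3)
  set.seed(7)
  ref <- matrix(rnorm(600, sd = 5), 200, 3)
  mob <- ref + matrix(rnorm(600, sd = 0.1), 200, 3)
  sup <- kabsch_superpose(mob, ref)
  expect_equal(sup$rmsd, 0.1 * sqrt(3), tolerance = 0.2)
})

test_that("structures beyond the 3.5 A gate or with too few shared atoms are excluded", {
  bed <- fixture_bed()
  ref <- resolve_altlocs(parse_mmcif(file.path(bed$cif_dir, "s12a.cif")))
  mob <- resolve_altlocs(parse_mmcif(file.path(bed$cif_dir, "s12b.cif")))
  sup <- superpose_to_reference(mob, ref)
  expect_false(sup$excluded)
  expect_lt(sup$rmsd, 0.5)

  # scramble the mobile coordinates far beyond the gate
  mob2 <- mob
  set.seed(3)
  mob2$atoms$x <- mob2$atoms$x + rnorm(nrow(mob2$atoms), sd = 6)
  mob2$atoms$y <- mob2$atoms$y + rnorm(nrow(mob2$atoms), sd = 6)
  sup2 <- superpose_to_reference(mob2, ref)
  expect_true(sup2$excluded)
  expect_equal(sup2$reason, "rmsd-gate")

  sup3 <- superpose_to_reference(mob, ref, chains = "Q")
  expect_true(sup3$excluded)
  expect_equal(sup3$reason, "too-few-paired-atoms")
})

test_that("ligand centroids are heavy-atom means and translation-equivariant", {
  p <- tempfile(fileext = ".cif")
  atoms <- data.frame(record = "HETATM", name = c("C1", "C2", "C3"),
                      element = "C", comp = "LIG", chain = "A", seq = 1L,
                      entity = "1", x = c(0, 2, 4), y = 0, z = 0)
  write_test_cif(p, "cen1", atoms,
                 data.frame(id = "1", type = "non-polymer", src = "syn"))
  s <- parse_mmcif(p)
  cand <- make_cand("LIG", seq0 = 1L)
  expect_equal(ligand_centroid(cand, s), c(2, 0, 0), ignore_attr = TRUE)

  t_sup <- list(rotation = diag(3), translation = c(1, 2, 3))
  expect_equal(ligand_centroid(cand, s, t_sup), c(3, 2, 3),
               ignore_attr = TRUE)

  s1 <- s
  s1$atoms <- s1$atoms[1, , drop = FALSE]
  s1$atoms$x <- 1; s1$atoms$y <- 2; s1$atoms$z <- 3
  expect_equal(ligand_centroid(cand, s1), c(1, 2, 3), ignore_attr = TRUE)
})

test_that("centroid clustering honors the 10 A threshold on both sides", {
  two_near <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(max(cluster_centroids(two_near)$cluster_id), 1L)
  two_far <- rbind(c(0, 0, 0), c(12, 0, 0))
  expect_equal(max(cluster_centroids(two_far)$cluster_id), 2L)

  set.seed(21)
  grp <- rbind(matrix(rnorm(24, sd = 1), 8, 3),
               sweep(matrix(rnorm(24, sd = 1), 8, 3), 2, c(30, 0, 0), "+"))
  cl <- cluster_centroids(grp)
  expect_equal(max(cl$cluster_id), 2L)
  expect_length(unique(cl$cluster_id[1:8]), 1L)
  expect_length(unique(cl$cluster_id[9:16]), 1L)
})

test_that("clustering satisfies the diameter/singleton properties and permutation invariance", {
  set.seed(33)
  for (trial in 1:20) {
    n <- sample(3:12, 1)
    pts <- matrix(runif(n * 3, 0, 4), n, 3)   # diameter < 10
    expect_equal(max(cluster_centroids(pts)$cluster_id), 1L)
    far <- matrix(0, n, 3)
    far[, 1] <- seq_len(n) * 15                # min gap > 10
    expect_equal(max(cluster_centroids(far)$cluster_id), n)
  }
  set.seed(34)
  pts <- rbind(matrix(rnorm(15), 5, 3),
               sweep(matrix(rnorm(15), 5, 3), 2, c(25, 0, 0), "+"))
  rownames(pts) <- paste0("m", 1:10)
  perm <- sample(10)
  cl1 <- cluster_centroids(pts)
  cl2 <- cluster_centroids(pts[perm, ])
  grp1 <- unname(split(cl1$member, cl1$cluster_id))
  grp2 <- unname(split(cl2$member, cl2$cluster_id))
  expect_setequal(lapply(grp1, sort), lapply(grp2, sort))
})

test_that("the summary file carries the documented columns in order", {
  rows <- data.frame(
    pdb_id = c("s001", "s005"), ligand_file = c("a.pdb", "b.pdb"),
    ligand_uid = c("LIG_A_201", "chain-E"),
    ligand_kind = c("small_molecule", "chain_peptide"),
    resolution = c(1.8, 1.8), uniprot = "P0TEST1", query_chains = "A",
    contact_chains = "A", n_nearby_residues = c(5L, 9L),
    flags = c("", "covalent"), cluster_id = NA_integer_,
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_summary(rows, f)
  out <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(names(out),
               c("pdb_id", "ligand_file", "ligand_uid", "ligand_kind",
                 "resolution", "uniprot", "query_chains", "contact_chains",
                 "n_nearby_residues", "flags", "cluster_id"))
  expect_equal(nrow(out), 2L)
  expect_match(out$flags[2], "covalent")
})
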