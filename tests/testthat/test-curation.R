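# Curation: chain classification, retention filters, trimming/renumbering,
# typing and the dataset summary FASTA.

toy_ref <- "ACDEFGHIKLMNPQRSTVWY"   # short stand-in reference for unit cases

test_that("chains classify by reference identity and peptide length", {
  entry <- make_complex(synthetic_complex_spec(seed = 1, include_b2m = TRUE))
  roles <- classify_chains(entry, reference_platform_sequence())
  expect_setequal(roles$role, c("heavy_chain", "b2m", "peptide"))
  expect_equal(roles$role[roles$chain == "A"], "heavy_chain")
  expect_equal(roles$role[roles$chain == "B"], "b2m")
  expect_equal(roles$role[roles$chain == "C"], "peptide")
  expect_gt(roles$identity[roles$chain == "A"], 0.5)
})

test_that("a 12-mer 'peptide' gets no peptide role and the entry is rejected", {
  entry <- make_complex(synthetic_complex_spec(seed = 1, peptide_length = 12,
                                               anchors = c(2, 9)))
  roles <- classify_chains(entry, reference_platform_sequence())
  expect_false("peptide" %in% roles$role)
  dec <- filter_entry(entry, roles)
  expect_false(dec$accept)
  expect_true("no_peptide" %in% dec$reasons)
})

test_that("a chain at 40% identity to the reference heavy chain is 'other'", {
  # 8 of 20 positions identical; global-alignment identity computed by hand
  # for these gap-free toy sequences is 8/20 = 0.4
  seq40 <- "ACDEFGHILVAAAAAAAAAA"
  ai <- align_identity(seq40, toy_ref)
  expect_equal(ai$identity, 0.4, tolerance = 0.051)
  expect_lt(ai$identity, 0.5)
  entry <- make_complex(synthetic_complex_spec(seed = 2))
  roles <- classify_chains(entry, reference_heavy = strrep(toy_ref, 9))
  expect_false("heavy_chain" %in% roles$role)
})

test_that("classification is invariant under chain reordering", {
  entry <- make_complex(synthetic_complex_spec(seed = 6, include_b2m = TRUE))
  roles1 <- classify_chains(entry, reference_platform_sequence())
  entry2 <- entry
  entry2$atoms <- entry2$atoms[order(match(entry2$atoms$chain,
                                           c("C", "B", "A"))), ]
  roles2 <- classify_chains(entry2, reference_platform_sequence())
  m1 <- setNames(roles1$role, roles1$chain)
  m2 <- setNames(roles2$role, roles2$chain)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("retention filters: contact rule, occupancy, resolution", {
  near <- make_complex(synthetic_complex_spec(seed = 4, extra_chain_dist = 3.9))
  rn <- classify_chains(near, reference_platform_sequence())
  expect_true("other_chain_contact" %in% filter_entry(near, rn)$reasons)

  far <- make_complex(synthetic_complex_spec(seed = 4, extra_chain_dist = 20))
  rf <- classify_chains(far, reference_platform_sequence())
  expect_true(filter_entry(far, rf)$accept)

  zo <- make_complex(synthetic_complex_spec(seed = 4))
  i <- which(zo$atoms$chain == "C" & zo$atoms$resno == 3 & zo$atoms$elety == "CA")
  zo$atoms$o[i] <- 0
  rz <- classify_chains(zo, reference_platform_sequence())
  expect_true("peptide_zero_occupancy" %in% filter_entry(zo, rz)$reasons)

  lo <- make_complex(synthetic_complex_spec(seed = 4, resolution = 3.4))
  rl <- classify_chains(lo, reference_platform_sequence())
  expect_true("resolution" %in% filter_entry(lo, rl)$reasons)
  # the cutoff itself is retained ("3.0 A or higher" quality)
  at <- make_complex(synthetic_complex_spec(seed = 4, resolution = 3.0))
  ra <- classify_chains(at, reference_platform_sequence())
  expect_true(filter_entry(at, ra)$accept)
})

test_that("missing peptide backbone atom rejects; heavy-chain zero occupancy only warns", {
  mi <- make_complex(synthetic_complex_spec(seed = 8))
  drop <- which(mi$atoms$chain == "C" & mi$atoms$resno == 6 & mi$atoms$elety == "O")
  mi$atoms <- mi$atoms[-drop, ]
  rm_ <- classify_chains(mi, reference_platform_sequence())
  expect_true("peptide_backbone_incomplete" %in% filter_entry(mi, rm_)$reasons)

  hw <- make_complex(synthetic_complex_spec(seed = 8))
  j <- which(hw$atoms$chain == "A" & hw$atoms$resno == 50 & hw$atoms$elety == "CA")
  hw$atoms$o[j] <- 0
  rh <- classify_chains(hw, reference_platform_sequence())
  dec <- filter_entry(hw, rh)
  expect_true(dec$accept)
  expect_true(dec$flags$heavy_chain_occupancy_warning)
})

test_that("renumbering removes author offsets and trims to the platform", {
  entry <- make_complex(synthetic_complex_spec(seed = 5, platform_offset = 1000L))
  res <- curate_entry(entry, reference_platform_sequence())
  expect_true(res$accepted)
  plat <- res$complex$atoms[res$complex$atoms$chain == "A", ]
  expect_equal(sort(unique(plat$resno)), 1:180)
  pep <- res$complex$atoms[res$complex$atoms$chain == "C", ]
  expect_equal(sort(unique(pep$resno)), 1:9)
})

test_that("an 8-mer peptide renumbers to positions 1-8", {
  cx <- make_curated(seed = 5, peptide_length = 8, anchors = c(2, 8))
  pep <- cx$atoms[cx$atoms$chain == "C", ]
  expect_equal(sort(unique(pep$resno)), 1:8)
  expect_equal(nchar(cx$peptide_sequence), 8)
})

test_that("typing returns the nearest allele with deterministic ties", {
  ref <- reference_platform_sequence()
  ty <- type_hla(ref, c("A*02:01" = ref))
  expect_equal(ty$allotype, "A*02:01")
  expect_equal(ty$identity, 1.0)
  # one substitution against A*02:01 in a two-allele reference: oracle
  # identities are 179/180 vs a far lower value for the divergent allele
  mut <- paste0("W", substr(ref, 2, 180))
  other <- paste0(substr(ref, 1, 90), strrep("K", 90))
  ty2 <- type_hla(mut, c("B*57:01" = other, "A*02:01" = ref))
  expect_equal(ty2$allotype, "A*02:01")
  expect_equal(ty2$identity, 179 / 180, tolerance = 1e-9)
  # exact tie breaks to the lexicographically smallest name
  ty3 <- type_hla(ref, c("Z*01:01" = ref, "A*02:01" = ref))
  expect_equal(ty3$allotype, "A*02:01")
  expect_error(type_hla(ref, character(0)))
  # typing failure below 50%
  ty4 <- type_hla(strrep("K", 180), c("A*02:01" = ref))
  expect_false(ty4$ok)
})

test_that("curation is idempotent on its own output", {
  cx <- make_curated(seed = 10, phi_sd = 6, psi_sd = 6)
  tmp <- tempfile(fileext = ".pdb")
  write_pdb_file(cx$atoms, tmp, pdb_id = cx$pdb_id,
                 resolution = cx$resolution, release_date = cx$release_date)
  re <- read_entry(tmp, pdb_id = cx$pdb_id)
  res2 <- curate_entry(re, reference_platform_sequence(), ref_fasta_path)
  expect_true(res2$accepted)
  cx2 <- res2$complex
  expect_equal(cx2$platform_sequence, cx$platform_sequence)
  expect_equal(cx2$peptide_sequence, cx$peptide_sequence)
  expect_equal(cx2$atoms[, c("chain", "resno", "elety")],
               cx$atoms[, c("chain", "resno", "elety")])
  expect_equal(as.matrix(cx2$atoms[, c("x", "y", "z")]),
               as.matrix(cx$atoms[, c("x", "y", "z")]), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(cx2$resolution, cx$resolution)
  expect_equal(cx2$release_date, cx$release_date)
  # accepted complexes re-satisfy the filters
  roles <- classify_chains(re, reference_platform_sequence())
  expect_true(filter_entry(re, roles)$accept)
})

test_that("summary FASTA round-trips all metadata fields", {
  cxs <- list(make_curated(seed = 1), make_curated(seed = 2, anchors = c(1, 9)))
  tmp <- tempfile(fileext = ".fasta")
  write_summary_fasta(cxs, tmp)
  tab <- read_summary_fasta(tmp)
  expect_equal(nrow(tab), 4)           # HLA + peptide per complex
  expect_setequal(tab$chain, c("HLA", "peptide"))
  expect_equal(tab$allotype[1], cxs[[1]]$allotype)
  expect_equal(tab$resolution[1], cxs[[1]]$resolution)
  expect_equal(tab$release_date[1], cxs[[1]]$release_date)
  expect_equal(tab$sequence[tab$chain == "peptide" & tab$pdb_id == "SYN1"][1],
               cxs[[1]]$peptide_sequence)
  # empty input -> empty output
  expect_length(write_summary_fasta(list()), 0)
})

test_that("curate_dir writes curated files, a summary and a rejection log", {
  ind <- tempfile("in")
  outd <- tempfile("out")
  dir.create(ind)
  make_complex(synthetic_complex_spec(seed = 1, pdb_id = "TOY1"),
               path = file.path(ind, "TOY1.pdb"))
  make_complex(synthetic_complex_spec(seed = 2, pdb_id = "TOY2",
                                      resolution = 3.5),
               path = file.path(ind, "TOY2.pdb"))
  cxs <- curate_dir(ind, ref_fasta_path, outd)
  expect_named(cxs, "TOY1")
  expect_true(file.exists(file.path(outd, "TOY1.pdb")))
  expect_true(file.exists(file.path(outd, "summary.fasta")))
  log <- read.delim(file.path(outd, "rejected.tsv"))
  expect_equal(log$pdb_id, "TOY2")
  expect_match(log$reason, "resolution")
})

test_that("the mmCIF reader reproduces the PDB-format atom table", {
  entry <- make_complex(synthetic_complex_spec(seed = 12))
  cif <- tempfile(fileext = ".cif")
  at <- entry$atoms
  con <- file(cif, "w")
  writeLines(c("data_SYN1", "#",
               "_refine.ls_d_res_high   2.00", "#", "loop_",
               paste0("_atom_site.", c("group_PDB", "label_atom_id",
                                       "label_alt_id", "auth_comp_id",
                                       "auth_asym_id", "auth_seq_id",
                                       "Cartn_x", "Cartn_y", "Cartn_z",
                                       "occupancy", "B_iso_or_equiv"))), con)
  writeLines(sprintf("ATOM %s . %s %s %d %.3f %.3f %.3f %.2f %.2f",
                     at$elety, at$resid, at$chain, at$resno,
                     at$x, at$y, at$z, at$o, at$b), con)
  writeLines("#", con)
  close(con)
  re <- read_entry(cif, pdb_id = "SYN1", release_date = "2020-01-01")
  expect_equal(re$resolution, 2.0)
  expect_equal(nrow(re$atoms), nrow(at))
  expect_equal(re$atoms$elety, at$elety)
  expect_equal(re$atoms$x, at$x, tolerance = 1e-3)
  res <- curate_entry(re, reference_platform_sequence())
  expect_true(res$accepted)
})
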