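test_that("polyprotein cleavage reproduces the 931 -> 264/251/416 partition", {
  prods <- cleave_polyprotein(931, c(264, 515), names = c("VP4A", "VP4B", "VP4C"))
  expect_identical(prods$length, c(264L, 251L, 416L))
  expect_identical(prods$start, c(1L, 265L, 516L))
  expect_identical(prods$end, c(264L, 515L, 931L))
  expect_identical(sum(prods$length), 931L)
})

test_that("cleavage handles edge cases and rejects bad sites", {
  expect_identical(cleave_polyprotein(10)$length, 10L)
  expect_identical(cleave_polyprotein(10, c(3, 7))$length, c(3L, 4L, 3L))
  expect_error(cleave_polyprotein(10, c(7, 3)), "ascending")
  expect_error(cleave_polyprotein(10, c(0, 5)), "inside")
  expect_error(cleave_polyprotein(10, c(5, 10)), "inside")
  expect_error(cleave_polyprotein(0), "length")
})

test_that("cleavage products always tile the polyprotein (property)", {
  set.seed(17)
  for (rep in 1:25) {
    len <- sample(5:2000, 1)
    k <- sample(0:4, 1)
    sites <- sort(sample(seq_len(len - 1), min(k, len - 1)))
    prods <- cleave_polyprotein(len, sites)
    expect_identical(sum(prods$length), as.integer(len))
    expect_identical(prods$start[-1], prods$end[-nrow(prods)] + 1L)
    expect_identical(prods$start[1], 1L)
    expect_identical(prods$end[nrow(prods)], as.integer(len))
  }
})

test_that("approximate masses match hand-summed closed forms", {
  expect_equal(approx_mass(""), 0.01801528, tolerance = 1e-8)
  expect_equal(approx_mass("GG"), 0.132, tolerance = 0.001)
  polyA <- strrep("A", 100)
  expect_equal(approx_mass(polyA), 7.126, tolerance = 0.001)
  expect_error(approx_mass("AC9G"), "position 3")
})

test_that("mass is additive over concatenation minus one water per junction", {
  s1 <- make_polyprotein(60, seed = 2)
  s2 <- make_polyprotein(40, seed = 3)
  water <- 0.01801528
  expect_equal(approx_mass(paste0(s1, s2)),
               approx_mass(s1) + approx_mass(s2) - water, tolerance = 1e-9)
})

test_that("sequence cleavage attaches sequences and masses", {
  seq <- make_polyprotein(931, seed = 8)
  prods <- cleave_polyprotein(seq, c(264, 515))
  expect_identical(nchar(prods$sequence), c(264L, 251L, 416L))
  expect_identical(paste(prods$sequence, collapse = ""), seq)
  expect_equal(prods$approx_mass_kda,
               vapply(prods$sequence, approx_mass, numeric(1), USE.NAMES = FALSE))
})

test_that("FASTA reader handles multi-record wrapped files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">polyprotein some description", "MKV", "LRA", ">frag2", "GG"), f)
  seqs <- read_fasta(f)
  expect_identical(seqs, c(polyprotein = "MKVLRA", frag2 = "GG"))
})

test_that("basic residues on the inner surface are found with axis annotation", {
  ops <- ico_ops()
  ax <- find_axes(ops)
  mk <- function(res_name, res_seq, atom, r_dir, radius, chain = "A") {
    d <- r_dir / sqrt(sum(r_dir^2))
    one_atom(atom, substr(atom, 1, 1), res_name, res_seq, chain, d * radius)
  }
  f2 <- as.numeric(ax[ax$order == 2, c("dx", "dy", "dz")][1, ])
  au <- structure_model(rbind(
    mk("LYS", 224, "NZ", c(1, 2, 3), 105),      # inside the shell
    mk("ARG", 78, "CZ", c(2, 1, 3), 104),
    mk("HIS", 9, "NE2", f2 * 1.02, 103),        # close to a two-fold axis
    mk("HIS", 50, "CB", c(1, 1, 1), 140),       # outside the shell
    mk("GLY", 1, "CA", c(3, 1, 1), 105)))       # not basic
  expanded <- expand_capsid(au, ops)
  sites <- basic_residue_map(expanded, ax, inner_shell = c(95, 115))
  expect_setequal(unique(sites$res_seq), c(9, 78, 224))
  expect_identical(nrow(sites), 3L * 60L)
  his <- sites[sites$res_seq == 9, ]
  expect_true(all(his$nearest_axis_order == 2))
  expect_true(all(his$nearest_axis_distance < 10))
  # shell excluding everything -> empty
  none <- basic_residue_map(expanded, ax, inner_shell = c(1, 5))
  expect_identical(nrow(none), 0L)
})

test_that("CB fallback is used when the terminal side-chain atom is missing", {
  ops <- ico_ops()
  au <- structure_model(rbind(
    one_atom("CB", "C", "LYS", 7, "A", c(0, 0, 100)),
    one_atom("CA", "C", "LYS", 8, "A", c(0, 0, 101))))  # no NZ, no CB either
  sites <- basic_residue_map(expand_capsid(au, ops), NULL, c(90, 110))
  expect_identical(sort(unique(sites$res_seq)), 7)
  expect_true(all(is.na(sites$nearest_axis_order)))
})

test_that("modeled-residue accounting mirrors a chain with disordered termini", {
  # VP4B-like: CA present for residues 2-242 of a declared 251
  atoms <- protein_chain_atoms("B", nres = 241, start_res = 2)
  m <- structure_model(atoms)
  acc <- modeled_residue_accounting(m, c(B = "VP4B"), c(VP4B = 251))
  expect_identical(acc$first_modeled, 2L)
  expect_identical(acc$last_modeled, 242L)
  expect_identical(acc$modeled, 241L)
  expect_identical(acc$expected, 251L)
  # a gap excludes its residues from the modeled count
  gap <- atoms[!(atoms$res_seq %in% 100:110 & atoms$name == "CA"), ]
  acc2 <- modeled_residue_accounting(structure_model(gap), c(B = "VP4B"),
                                     c(VP4B = 251))
  expect_identical(acc2$modeled, 230L)
  # full chain: modeled = expected
  full <- modeled_residue_accounting(
    structure_model(protein_chain_atoms("A", nres = 264)),
    c(A = "VP4A"), c(VP4A = 264))
  expect_identical(full$modeled, full$expected)
  expect_error(modeled_residue_accounting(m, c(Z = "VP4A"), c(VP4A = 264)),
               "no CA")
})
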