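# Shared fixtures, built in code. Heavier ones are memoised per test run.

# a minimal protein-like atom table: one chain, `nres` residues x 4 backbone
# atoms, laid out on a line so selections are countable by construction
protein_chain_atoms <- function(chain = "A", nres = 13, start_res = 1,
                                res_name = "ALA", x0 = 0) {
  atoms <- expand.grid(atom = c("N", "CA", "C", "O"),
                       res = seq(start_res, length.out = nres))
  n <- nrow(atoms)
  data.frame(
    serial = seq_len(n),
    name = as.character(atoms$atom),
    element = substr(as.character(atoms$atom), 1, 1),
    res_name = res_name,
    res_seq = atoms$res,
    chain_id = chain,
    x = x0 + seq_len(n) * 1.5, y = 0, z = 0,
    occupancy = 1, b_factor = 10,
    stringsAsFactors = FALSE)
}

# single free-standing atom at a position
one_atom <- function(name = "CB", element = "C", res_name = "THR",
                     res_seq = 114, chain = "A", pos = c(0, 0, 0)) {
  data.frame(serial = 1L, name = name, element = element, res_name = res_name,
             res_seq = res_seq, chain_id = chain,
             x = pos[1], y = pos[2], z = pos[3],
             occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
}

# memoised seeded shell fixtures (shared across test files)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

shell_100_130 <- function() cached("shell_100_130",
  make_shell_capsid(100, 130, atoms_per_au = 500, seed = 42))

dense_shell <- function() cached("dense_shell",
  make_shell_capsid(100, 110, surface_coverage = 2.5, seed = 11))

ico_ops <- function() cached("ico_ops", icosahedral_operators())

# brute-force all-pairs contact oracle, independent of the cell-list path
brute_force_contacts <- function(a, b, cutoff) {
  if (nrow(a) == 0 || nrow(b) == 0 || cutoff <= 0) return(NULL)
  dx <- outer(a$x, b$x, "-"); dy <- outer(a$y, b$y, "-"); dz <- outer(a$z, b$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  i <- hit[, 1]; j <- hit[, 2]
  same <- a$chain_id[i] == b$chain_id[j] & a$res_seq[i] == b$res_seq[j]
  i <- i[!same]; j <- j[!same]
  if (length(i) == 0) return(NULL)
  key <- paste(a$chain_id[i], a$res_seq[i], b$chain_id[j], b$res_seq[j], sep = "\r")
  data.frame(key = sort(unique(key)),
             min_distance = as.numeric(tapply(d[cbind(i, j)], key, min)[sort(unique(key))]),
             n_atom_pairs = as.integer(tapply(key, key, length)[sort(unique(key))]),
             stringsAsFactors = FALSE)
}
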