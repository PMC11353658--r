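# Shared fixtures built in code.

kr_rule <- function() protease_rule("trypsin-like", list(p1 = c("K", "R")))

random_sequence <- function(len) {
  paste(sample(pepsilico:::AA_ALPHABET, len, replace = TRUE), collapse = "")
}

tiny_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  write_fasta(records, path)
  path
}

tiny_motif_tsv <- function(db) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_complex_file <- function(toy) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  write_toy_complex(toy, path)
  path
}

# Independent brute-force oracles, deliberately naive.
oracle_cleavage_scan <- function(sequence, rule) {
  chars <- strsplit(sequence, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(nchar(sequence) - 1L)) {
    for (s in rule$sites) {
      ok <- chars[i] %in% s$p1 &&
        (!length(s$p1prime) || chars[i + 1L] %in% s$p1prime)
      if (ok) { hits <- c(hits, i); break }
    }
  }
  hits
}

oracle_substring_count <- function(sequence, fragment) {
  n <- 0L
  for (i in seq_len(max(0L, nchar(sequence) - nchar(fragment) + 1L)))
    if (substr(sequence, i, i + nchar(fragment) - 1L) == fragment)
      n <- n + 1L
  n
}

oracle_contacts <- function(atoms_a, atoms_b, cutoff) {
  # all-pairs residue contact scan, O(n^2) over atoms
  pairs <- character(0)
  for (i in seq_len(nrow(atoms_a))) {
    for (j in seq_len(nrow(atoms_b))) {
      d <- sqrt((atoms_a$x[i] - atoms_b$x[j])^2 +
                (atoms_a$y[i] - atoms_b$y[j])^2 +
                (atoms_a$z[i] - atoms_b$z[j])^2)
      if (d <= cutoff)
        pairs <- c(pairs, paste(atoms_a$resno[i], atoms_b$resno[j], sep = "~"))
    }
  }
  unique(pairs)
}
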