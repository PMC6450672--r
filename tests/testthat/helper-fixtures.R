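# Shared fixtures: the tau constructs shipped with the package and small
# model builders reused across tests.

tau_fasta_path <- function() {
  system.file("extdata", "tau_constructs_synthetic.fasta",
              package = "coacervate")
}

tau_constructs <- function() read_charged_fasta(tau_fasta_path())

tau187_seq <- function() tau_constructs()[[1]]      # bare 187-mer
tau187his_seq <- function() tau_constructs()[[2]]   # tagged 207-mer

# truncated tau fragment + matched polyU for affordable field-theory runs
truncated_pair <- function(n = 20) {
  tau <- tau187_seq()
  list(tau = assign_charges(paste(tau$residues[seq_len(n)], collapse = "")),
       rna = make_polyU(n))
}

# neutral homopolymer chain for ideal / mean-field limits
neutral_chain <- function(n = 20) {
  assign_charges(paste(rep("G", n), collapse = ""))
}

expect_complex_equal <- function(x, y, tol = 1e-12) {
  expect_lt(Mod(x - y), tol * max(1, Mod(y)))
}
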