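# Per-residue charge model shared by the lattice (FH-VO) and field-theoretic
# tracks: at pH 7 only D/E (-1) and K/R (+1) carry integer charge; H, C, S and
# everything else are neutral. polyU RNA is one -1 charge per nucleotide.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.aa_charge <- c(D = -1L, E = -1L, K = 1L, R = 1L)

#' Assign integer per-residue charges to a protein sequence
#'
#' Builds a `charged_sequence`: the per-monomer charge vector used by both the
#' lattice model (through its average charge density) and the field-theoretic
#' model (monomer by monomer). At neutral pH, aspartate and glutamate carry
#' -1, lysine and arginine +1, and all other residues (including histidine
#' and cysteine) are neutral.
#'
#' @param sequence Amino-acid string (one-letter codes, 20-residue alphabet)
#'   or a character vector of single letters.
#' @param pH Solution pH. Only 7 is supported by the integer model; the value
#'   is stored for bookkeeping.
#' @return A `charged_sequence`: list with `residues` (character vector), `z`
#'   (integer charges, elementary units), `N` (chain length), `q_net`
#'   (net charge) and `sigma` (`|q_net|/N`, charges per monomer).
#' @seealso [make_polyU()], [phosphorylate()], [net_charge_hh()] for a
#'   fractional Henderson-Hasselbalch estimate (documentation only).
#' @export
#' @examples
#' assign_charges("DE")$q_net   # -2
#' assign_charges("GASG")$q_net # 0
assign_charges <- function(sequence, pH = 7) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(as.character(sequence))
  if (length(sequence) == 0L || !nzchar(paste(sequence, collapse = "")))
    stop("sequence must be non-empty")
  bad <- which(!(sequence %in% .aa_alphabet))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", sequence[bad[1]], bad[1]))
  z <- unname(.aa_charge[sequence])
  z[is.na(z)] <- 0L
  z <- as.integer(z)
  new_charged_sequence(sequence, z, pH = pH)
}

new_charged_sequence <- function(residues, z, pH = 7, label = NULL) {
  stopifnot(length(residues) == length(z))
  q <- sum(z)
  structure(list(residues = residues, z = z, N = length(z),
                 q_net = q, sigma = abs(q) / length(z),
                 pH = pH, label = label),
            class = "charged_sequence")
}

#' @export
print.charged_sequence <- function(x, ...) {
  cat(sprintf("charged_sequence: N = %d, q_net = %+d, sigma = %.4f\n",
              x$N, x$q_net, x$sigma))
  head <- paste(utils::head(x$residues, 30), collapse = "")
  cat(sprintf("  %s%s\n", head, if (x$N > 30) "..." else ""))
  invisible(x)
}

#' Fully charged polyU RNA chain
#'
#' polyU is modelled as a fully charged polyanion: one -1 charge per
#' nucleotide, so `sigma = 1` at every length.
#'
#' @param N Number of nucleotides (>= 1).
#' @return A `charged_sequence` with all charges -1.
#' @export
#' @examples
#' make_polyU(5)$q_net  # -5
make_polyU <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1)
    stop("N must be a single integer >= 1")
  N <- as.integer(N)
  new_charged_sequence(rep("U", N), rep(-1L, N), label = "polyU")
}

#' polyU chain length from molecular weight
#'
#' Converts an RNA mass to a monomer count using the residue mass of
#' condensed uridine monophosphate (306 Da), flooring to an integer.
#'
#' @param mass_Da RNA molecular weight in Da.
#' @param monomer_mass_Da Residue mass, default 306 Da.
#' @return Integer monomer count.
#' @export
#' @examples
#' polyU_length_from_mass(9e5)  # 2941
polyU_length_from_mass <- function(mass_Da, monomer_mass_Da = 306) {
  stopifnot(mass_Da > 0, monomer_mass_Da > 0)
  as.integer(floor(mass_Da / monomer_mass_Da))
}

#' Phosphorylate serine residues of a charged sequence
#'
#' Models complete phosphorylation as a -2 charge on each listed serine
#' (phosphoserine at neutral pH), the limiting case used for charge-variant
#' simulations.
#'
#' @param seq A `charged_sequence`.
#' @param sites Integer positions (1-based along the stored sequence); every
#'   site must be a serine.
#' @return The modified `charged_sequence`.
#' @export
#' @examples
#' s <- assign_charges("GSGSG")
#' phosphorylate(s, c(2, 4))$q_net  # -4
phosphorylate <- function(seq, sites) {
  stopifnot(inherits(seq, "charged_sequence"))
  if (length(sites) == 0L) return(seq)
  sites <- as.integer(sites)
  if (any(sites < 1L | sites > seq$N))
    stop("phosphorylation site out of range")
  notS <- sites[seq$residues[sites] != "S"]
  if (length(notS))
    stop(sprintf("position %d is '%s', not serine", notS[1],
                 seq$residues[notS[1]]))
  z <- seq$z
  z[sites] <- -2L
  new_charged_sequence(seq$residues, z, pH = seq$pH, label = seq$label)
}

#' Charge-matched RNA mass concentration for a tau solution
#'
#' Under the 1:1 charge-matching condition the nucleotide molar concentration
#' equals `q_tau` times the tau molar concentration; converting with the
#' nucleotide residue mass gives the RNA mass concentration to mix.
#'
#' @param tau_conc_uM Tau concentration in micromolar.
#' @param q_tau Net positive charge per tau molecule (elementary charges).
#' @param monomer_mass_Da Nucleotide residue mass, default 306 Da.
#' @return RNA mass concentration in micrograms per millilitre.
#' @export
#' @examples
#' charge_matched_rna_mass(1, 11)   # ~3.4 ug/mL ("1 uM : 3 ug/mL" rule)
#' charge_matched_rna_mass(50, 11)  # ~168 ug/mL
charge_matched_rna_mass <- function(tau_conc_uM, q_tau, monomer_mass_Da = 306) {
  stopifnot(all(tau_conc_uM >= 0), q_tau > 0, monomer_mass_Da > 0)
  # uM * (charges/molecule) * (g/mol) -> ug/mL carries a factor 1e-3
  tau_conc_uM * q_tau * monomer_mass_Da * 1e-3
}

# Standard side-chain / terminus pKa values (Lehninger set) for the
# documentation-only fractional estimate.
.pka <- list(D = 3.65, E = 4.25, C = 8.3, Y = 10.07, H = 6.0,
             K = 10.53, R = 12.48, Nterm = 8.95, Cterm = 3.1)

#' Fractional net charge by Henderson-Hasselbalch (documentation only)
#'
#' Titration-style estimate of the net charge of a protein sequence,
#' including fractional histidine and terminal contributions. This is the
#' kind of calculator estimate that yields "+11" for the tau187 construct; it
#' is reported for documentation and is never used by the integer
#' field-theoretic charge model (see [assign_charges()]).
#'
#' @param sequence Amino-acid string.
#' @param pH Solution pH (default 7).
#' @param termini Include N/C terminal charges (default TRUE).
#' @return Fractional net charge (elementary charges).
#' @export
net_charge_hh <- function(sequence, pH = 7, termini = TRUE) {
  res <- assign_charges(sequence)$residues
  frac_pos <- function(pka) 1 / (1 + 10^(pH - pka))   # basic group
  frac_neg <- function(pka) -1 / (1 + 10^(pka - pH))  # acidic group
  q <- 0
  for (a in c("K", "R", "H"))
    q <- q + sum(res == a) * frac_pos(.pka[[a]])
  for (a in c("D", "E", "C", "Y"))
    q <- q + sum(res == a) * frac_neg(.pka[[a]])
  if (termini) q <- q + frac_pos(.pka$Nterm) + frac_neg(.pka$Cterm)
  q
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet` returning
#' `charged_sequence` objects (one per record).
#'
#' @param file Path to a FASTA file (single- or multi-record).
#' @return Named list of `charged_sequence` objects.
#' @export
read_charged_fasta <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  out <- lapply(seq_along(aa), function(i) {
    cs <- assign_charges(as.character(aa[[i]]))
    cs$label <- names(aa)[i]
    cs
  })
  names(out) <- names(aa)
  out
}

#' Write a per-position charge table
#'
#' Plain-text (TSV) table of position, residue and integer charge, the
#' interchange format consumed by downstream charge-sequence tools.
#'
#' @param seq A `charged_sequence`.
#' @param file Output path.
#' @return The table, invisibly.
#' @export
write_charge_table <- function(seq, file) {
  stopifnot(inherits(seq, "charged_sequence"))
  tab <- data.frame(position = seq_len(seq$N), residue = seq$residues,
                    z = seq$z)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Species specification for the lattice model
#'
#' Describes one of the five lattice species (polycation, polyanion, cation,
#' anion, solvent) by its degree of polymerization `N` and average charge per
#' monomer `sigma`. Ions and solvent have `N = 1`; solvent has `sigma = 0`,
#' monovalent ions `sigma = 1`.
#'
#' @param name Species name.
#' @param role One of `"polycation"`, `"polyanion"`, `"cation"`, `"anion"`,
#'   `"solvent"`.
#' @param N Degree of polymerization.
#' @param sigma Average charge magnitude per monomer.
#' @return A `species_spec` object.
#' @export
species_spec <- function(name, role, N, sigma) {
  role <- match.arg(role, c("polycation", "polyanion", "cation", "anion",
                            "solvent"))
  stopifnot(N >= 1, sigma >= 0)
  if (role %in% c("cation", "anion", "solvent") && N != 1)
    stop("ions and solvent must have N = 1")
  if (role == "solvent" && sigma != 0) stop("solvent must have sigma = 0")
  if (role %in% c("cation", "anion") && sigma != 1)
    stop("monovalent ions must have sigma = 1")
  structure(list(name = name, role = role, N = N, sigma = sigma),
            class = "species_spec")
}
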