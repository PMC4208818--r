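# IQ / 1-5-10 / 1-8-14 motif scanning and IQ67 domain calling.
#
# The IQ67 domain of plant IQD proteins spans 67 residues and carries 1-3
# copies of the Ca2+-independent IQ motif (strict form IQxxxRGxxxR, relaxed
# form [ILV]QxxxRxxxx[RK]) at a canonical spacing of 11 and 15 intervening
# residues, overlapping 1-4 copies of the Ca2+-dependent 1-5-10 motif
# ([FILVW]x3[FILV]x4[FILVW]) and 1-8-14 motif ([FILVW]x6[FAILVW]x5[FILVW]).

.MOTIF_PATTERNS <- list(
  IQ_strict = list(regex = "IQ...RG...R", len = 11L),
  IQ_relaxed = list(regex = "[ILV]Q...R....[RK]", len = 11L),
  M_1_5_10 = list(regex = "[FILVW]...[FILV]....[FILVW]", len = 10L),
  M_1_8_14 = list(regex = "[FILVW]......[FAILVW].....[FILVW]", len = 14L)
)

#' Motif classes recognized by the scanner
#' @return Character vector of motif class names.
#' @export
motif_classes <- function() names(.MOTIF_PATTERNS)

#' Scan a protein for calmodulin-recruitment motifs
#'
#' Finds all (possibly overlapping) windows matching the requested motif
#' class. Matching is done with a zero-width lookahead so overlapping hits
#' are reported; hits are sorted by start.
#'
#' @param protein A protein [seq_record()] (or plain character string).
#' @param motif_class One of `"IQ_strict"`, `"IQ_relaxed"`, `"M_1_5_10"`,
#'   `"M_1_8_14"`.
#' @return A data frame with columns `motif_class`, `start`, `end` (1-based
#'   inclusive protein coordinates) and `matched_seq`; zero rows when there
#'   is no hit.
#' @examples
#' scan_motif(seq_record("p", "IQAAARGAAAR", "protein"), "IQ_strict")
#' @export
scan_motif <- function(protein, motif_class = motif_classes()) {
  motif_class <- match.arg(motif_class)
  if (inherits(protein, "seq_record")) {
    if (protein$alphabet != "protein") {
      stop("scan_motif requires a protein sequence; got alphabet '",
           protein$alphabet, "'")
    }
    s <- protein$sequence
  } else {
    s <- toupper(as.character(protein))
  }
  pat <- .MOTIF_PATTERNS[[motif_class]]
  m <- gregexpr(paste0("(?=(", pat$regex, "))"), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(motif_class = character(0), start = integer(0),
                      end = integer(0), matched_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  data.frame(motif_class = motif_class,
             start = starts,
             end = starts + pat$len - 1L,
             matched_seq = substring(s, starts, starts + pat$len - 1L),
             stringsAsFactors = FALSE)
}

#' Call complete IQ67 domains in a protein
#'
#' A candidate domain is any 67-residue window anchored at the first residue
#' of a relaxed-IQ hit and fully contained in the protein. Overlapping calls
#' are merged with the leftmost kept. For each called domain, IQ (relaxed),
#' strict-IQ, 1-5-10 and 1-8-14 hits within the window are recorded, and
#' `spacing_ok` is `TRUE` when successive IQ hits are separated by 11 and 15
#' intervening residues (within `spacing_tolerance`).
#'
#' @param protein A protein [seq_record()].
#' @param spacing_tolerance Allowed deviation (residues) from the canonical
#'   11/15 intervening-residue spacing (default 2).
#' @param min_iq_copies Minimum number of IQ (relaxed) hits required inside
#'   the window for a call (default 1, matching the 1-3 copy range).
#' @return A list of `iq67_domain` objects, each a list with fields
#'   `start`, `end`, `iq_hits`, `iq_strict_hits`, `m1510_hits`,
#'   `m1814_hits` (data frames as from [scan_motif()]) and `spacing_ok`.
#'   Proteins shorter than 67 residues yield an empty list with a warning.
#' @export
call_iq67_domains <- function(protein, spacing_tolerance = 2L,
                              min_iq_copies = 1L) {
  if (inherits(protein, "seq_record")) {
    n <- seq_length(protein)
  } else {
    protein <- seq_record("query", protein, "protein")
    n <- seq_length(protein)
  }
  if (n < 67L) {
    warning("protein '", protein$id, "' is shorter than 67 residues (", n,
            "); no IQ67 domain can be called")
    return(list())
  }
  relaxed <- scan_motif(protein, "IQ_relaxed")
  if (nrow(relaxed) == 0L) return(list())
  strict <- scan_motif(protein, "IQ_strict")
  m1510 <- scan_motif(protein, "M_1_5_10")
  m1814 <- scan_motif(protein, "M_1_8_14")

  within <- function(hits, lo, hi) {
    hits[hits$start >= lo & hits$end <= hi, , drop = FALSE]
  }
  domains <- list()
  last_end <- 0L
  for (anchor in relaxed$start) {
    lo <- anchor
    hi <- anchor + 66L
    if (hi > n) next
    if (lo <= last_end) next  # merge overlapping calls, leftmost kept
    iq <- within(relaxed, lo, hi)
    if (nrow(iq) < min_iq_copies) next
    gaps <- if (nrow(iq) > 1L) {
      iq$start[-1L] - iq$end[-nrow(iq)] - 1L
    } else integer(0)
    spacing_ok <- nrow(iq) >= 3L &&
      all(abs(gaps[1:2] - c(11L, 15L)) <= spacing_tolerance)
    dom <- structure(list(start = lo, end = hi,
                          iq_hits = iq,
                          iq_strict_hits = within(strict, lo, hi),
                          m1510_hits = within(m1510, lo, hi),
                          m1814_hits = within(m1814, lo, hi),
                          spacing_ok = spacing_ok),
                     class = "iq67_domain")
    domains[[length(domains) + 1L]] <- dom
    last_end <- hi
  }
  domains
}

#' @export
print.iq67_domain <- function(x, ...) {
  cat(sprintf(
    "<iq67_domain %d-%d: %d IQ (%d strict), %d 1-5-10, %d 1-8-14, spacing_ok=%s>\n",
    x$start, x$end, nrow(x$iq_hits), nrow(x$iq_strict_hits),
    nrow(x$m1510_hits), nrow(x$m1814_hits), x$spacing_ok))
  invisible(x)
}

# Average residue masses (Da) and water, standard 20-letter alphabet.
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01524

# EMBOSS-style pKa values for the ionizable groups.
.DEFAULT_PKA <- c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
                  D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the two termini and the ionizable side
#' chains (K, R, H positive; D, E, C, Y negative).
#'
#' @param counts Named integer vector of residue counts (names = one-letter
#'   codes).
#' @param ph pH value(s).
#' @param pka Named pKa vector; see `protein_properties`.
#' @return Net charge at each `ph`.
#' @export
protein_net_charge <- function(counts, ph, pka = .DEFAULT_PKA) {
  pos_charge <- function(pk, n) n / (1 + 10^(ph - pk))
  neg_charge <- function(pk, n) n / (1 + 10^(pk - ph))
  cnt <- function(a) if (a %in% names(counts)) counts[[a]] else 0L
  pos_charge(pka[["Nterm"]], 1L) +
    pos_charge(pka[["K"]], cnt("K")) +
    pos_charge(pka[["R"]], cnt("R")) +
    pos_charge(pka[["H"]], cnt("H")) -
    neg_charge(pka[["Cterm"]], 1L) -
    neg_charge(pka[["D"]], cnt("D")) -
    neg_charge(pka[["E"]], cnt("E")) -
    neg_charge(pka[["C"]], cnt("C")) -
    neg_charge(pka[["Y"]], cnt("Y"))
}

#' Protein-level descriptors: length, molecular weight, pI, serine content
#'
#' Molecular weight is the sum of average residue masses plus one water;
#' the isoelectric point is the root of the net-charge function, solved by
#' bisection on pH 0-14 under the configured pKa table.
#'
#' @param protein A protein [seq_record()] or character string restricted to
#'   the standard 20-letter alphabet.
#' @param pka Named pKa vector with entries `Nterm`, `Cterm`, `K`, `R`, `H`,
#'   `D`, `E`, `C`, `Y` (EMBOSS-style defaults).
#' @param tol Bisection convergence tolerance on pH (default 1e-6).
#' @return A list with `length` (aa), `molecular_weight` (kDa),
#'   `isoelectric_point` (pH units) and `serine_fraction`.
#' @examples
#' protein_properties("SSSS")$serine_fraction  # 1
#' @export
protein_properties <- function(protein, pka = .DEFAULT_PKA, tol = 1e-6) {
  s <- if (inherits(protein, "seq_record")) protein$sequence else toupper(protein)
  chars <- strsplit(s, "")[[1L]]
  bad <- which(!chars %in% names(.AA_MASS))
  if (length(bad) > 0L) {
    stop("non-standard residue '", chars[bad[1L]], "' at position ", bad[1L])
  }
  counts <- table(factor(chars, levels = names(.AA_MASS)))
  counts <- stats::setNames(as.integer(counts), names(.AA_MASS))
  mw_da <- sum(counts * .AA_MASS) + .WATER_MASS
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, mid, pka) > 0) lo <- mid else hi <- mid
  }
  list(length = length(chars),
       molecular_weight = mw_da / 1000,
       isoelectric_point = (lo + hi) / 2,
       serine_fraction = counts[["S"]] / length(chars))
}

#' Protein length implied by an ORF length
#'
#' The ORF length includes the stop codon, so an ORF of `orf_bp` base pairs
#' encodes `orf_bp / 3 - 1` amino acids (e.g. 1263 bp -> 420 aa).
#'
#' @param orf_bp ORF length(s) in base pairs, divisible by 3.
#' @return Protein length(s) in amino acids.
#' @export
orf_to_protein_length <- function(orf_bp) {
  if (any(orf_bp %% 3 != 0)) stop("ORF length must be divisible by 3")
  as.integer(orf_bp / 3 - 1)
}

#' Tabulate IQ67 domain calls for a set of proteins
#'
#' Convenience wrapper running [call_iq67_domains()] over a list of protein
#' records and returning one row per called domain.
#'
#' @param proteins Named list of protein [seq_record()]s.
#' @inheritParams call_iq67_domains
#' @return Data frame with columns `protein_id`, `dom_start`, `dom_end`,
#'   `n_iq`, `n_iq_strict`, `n_1510`, `n_1814`, `spacing_ok`.
#' @export
scan_proteome <- function(proteins, spacing_tolerance = 2L, min_iq_copies = 1L) {
  rows <- list()
  for (p in proteins) {
    doms <- if (seq_length(p) < 67L) list() else {
      call_iq67_domains(p, spacing_tolerance, min_iq_copies)
    }
    for (d in doms) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p$id, dom_start = d$start, dom_end = d$end,
        n_iq = nrow(d$iq_hits), n_iq_strict = nrow(d$iq_strict_hits),
        n_1510 = nrow(d$m1510_hits), n_1814 = nrow(d$m1814_hits),
        spacing_ok = d$spacing_ok, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(0), dom_start = integer(0),
                      dom_end = integer(0), n_iq = integer(0),
                      n_iq_strict = integer(0), n_1510 = integer(0),
                      n_1814 = integer(0), spacing_ok = logical(0)))
  }
  do.call(rbind, rows)
}
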