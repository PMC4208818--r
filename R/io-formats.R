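# Readers/writers for FASTA and GFF3, the package's internal sequence and
# gene-model containers, and the coordinate convention enforced throughout:
# genomic intervals are stored 0-based half-open; conversion to/from the
# 1-based inclusive conventions of GFF3 and protein coordinates happens only
# at I/O boundaries.

.DNA_CORE <- c("A", "C", "G", "T")
.DNA_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "U")
.AA_CORE <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")
.AA_AMBIG <- c("B", "Z", "X", "J", "U", "O", "*")

#' Construct a sequence record
#'
#' Light container for a single named sequence with a declared alphabet.
#' IUPAC ambiguity codes are tolerated but flagged via the `has_ambiguity`
#' attribute; characters outside the declared alphabet are an error.
#'
#' @param id Character identifier.
#' @param sequence Residue string (upper-cased on construction).
#' @param alphabet `"dna"` or `"protein"`.
#' @return An object of class `seq_record` with fields `id`, `sequence`,
#'   `alphabet` and logical attribute `has_ambiguity`.
#' @examples
#' seq_record("g1", "ATGCCC", "dna")
#' @export
seq_record <- function(id, sequence, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) {
    stop("sequence for '", id, "' is empty")
  }
  core <- if (alphabet == "dna") .DNA_CORE else .AA_CORE
  ambig <- if (alphabet == "dna") .DNA_AMBIG else .AA_AMBIG
  chars <- unique(strsplit(sequence, "")[[1L]])
  bad <- setdiff(chars, c(core, ambig))
  if (length(bad) > 0L) {
    stop("sequence for '", id, "' contains characters outside the ",
         alphabet, " alphabet: ", paste(bad, collapse = ", "))
  }
  rec <- structure(list(id = id, sequence = sequence, alphabet = alphabet),
                   class = "seq_record")
  attr(rec, "has_ambiguity") <- any(chars %in% ambig)
  rec
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s [%s], %d residues>\n",
              x$id, x$alphabet, nchar(x$sequence)))
  invisible(x)
}

#' Sequence length of a record
#' @param rec A `seq_record`.
#' @return Integer number of residues.
#' @export
seq_length <- function(rec) nchar(rec$sequence)

.guess_alphabet <- function(sequences) {
  chars <- unique(strsplit(paste(toupper(sequences), collapse = ""), "")[[1L]])
  if (all(chars %in% c(.DNA_CORE, .DNA_AMBIG))) "dna" else "protein"
}

#' Read a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()] and returns a list of
#' [seq_record()] objects, one per header, in file order.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"auto"` (default, guessed from residue content),
#'   `"dna"` or `"protein"`.
#' @return Named list of `seq_record` objects.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- as.character(set)
  if (alphabet == "auto") alphabet <- .guess_alphabet(seqs)
  recs <- lapply(seq_along(ids), function(i) {
    seq_record(ids[[i]], seqs[[i]], alphabet)
  })
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' @param records List of `seq_record` objects (or a single record).
#' @param path Output path.
#' @param width Line-wrap width (default 80 columns).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 80L) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$sequence, character(1L))
  ids <- vapply(records, function(r) r$id, character(1L))
  set <- Biostrings::BStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

.valid_interval_matrix <- function(m, what, gene_id) {
  if (!is.matrix(m) || ncol(m) != 2L || nrow(m) == 0L) {
    stop(what, " for '", gene_id, "' must be a two-column matrix")
  }
  if (any(m[, 1L] < 0L) || any(m[, 2L] <= m[, 1L])) {
    stop(what, " for '", gene_id, "' contain invalid 0-based half-open intervals")
  }
  m <- m[order(m[, 1L]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L])) {
    stop(what, " for '", gene_id, "' overlap")
  }
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  m
}

#' Construct a gene model
#'
#' Stores one gene's chromosome, strand and exon/CDS intervals. Intervals
#' are 0-based half-open in genome coordinates and kept sorted 5'->3' along
#' the genome regardless of strand; transcription order is derived from the
#' strand where needed.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of exon (start, end), 0-based half-open.
#' @param cds_segments Two-column matrix of CDS (start, end); every segment
#'   must be contained in an exon. Defaults to `exons`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons,
                       cds_segments = exons) {
  if (!strand %in% c("+", "-")) {
    stop("unknown strand symbol '", strand, "' for gene '", gene_id, "'")
  }
  exons <- .valid_interval_matrix(exons, "exons", gene_id)
  cds_segments <- .valid_interval_matrix(cds_segments, "CDS segments", gene_id)
  for (i in seq_len(nrow(cds_segments))) {
    covered <- any(exons[, 1L] <= cds_segments[i, 1L] &
                   exons[, 2L] >= cds_segments[i, 2L])
    if (!covered) {
      stop("CDS segment (", cds_segments[i, 1L], ", ", cds_segments[i, 2L],
           ") of gene '", gene_id, "' lies outside all exons")
    }
  }
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 exons = exons, cds_segments = cds_segments),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s %s:%d-%d (%s), %d exon(s), CDS %d nt>\n",
              x$gene_id, x$chromosome, gene_start(x), gene_end(x), x$strand,
              nrow(x$exons), cds_length(x)))
  invisible(x)
}

#' Genomic span accessors for a gene model
#' @param gene A `gene_model`.
#' @return 0-based start / half-open end of the gene's exon span.
#' @export
gene_start <- function(gene) min(gene$exons[, 1L])

#' @rdname gene_start
#' @export
gene_end <- function(gene) max(gene$exons[, 2L])

#' Total coding length of a gene model (nt)
#' @param gene A `gene_model`.
#' @return Integer sum of CDS segment lengths.
#' @export
cds_length <- function(gene) sum(gene$cds_segments[, 2L] - gene$cds_segments[, 1L])

#' Construct an annotation
#'
#' A set of gene models plus chromosome lengths and optional per-gene class
#' tags (`protein_coding`, `retroelement`, `transposon`) used when synteny
#' segments are filtered.
#'
#' @param genes List of `gene_model` objects.
#' @param chromosome_lengths Named numeric vector, chromosome -> length (bp).
#' @param gene_class_tags Optional named character vector, gene_id -> class.
#' @return An object of class `annotation`.
#' @export
annotation <- function(genes, chromosome_lengths, gene_class_tags = NULL) {
  ids <- vapply(genes, function(g) g$gene_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(genes) <- ids
  for (g in genes) {
    len <- chromosome_lengths[[g$chromosome]]
    if (is.null(len) || is.na(len)) {
      stop("gene '", g$gene_id, "' on unknown chromosome '", g$chromosome, "'")
    }
    if (gene_end(g) > len) {
      stop("gene '", g$gene_id, "' extends beyond chromosome '",
           g$chromosome, "' (", len, " bp)")
    }
  }
  structure(list(genes = genes,
                 chromosome_lengths = chromosome_lengths,
                 gene_class_tags = gene_class_tags),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation: %d gene(s) on %d chromosome(s)>\n",
              length(x$genes), length(x$chromosome_lengths)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features via [rtracklayer::import()] and
#' assembles one [gene_model()] per gene. GFF3 1-based inclusive coordinates
#' are converted to the internal 0-based half-open convention. When a gene
#' has several mRNAs the first listed one is used, with a warning.
#' Chromosome lengths come from `##sequence-region` directives when present,
#' otherwise from the maximal feature end per chromosome.
#'
#' @param path Path to a GFF3 file.
#' @return An [annotation()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  strand_chr <- as.character(GenomicRanges::strand(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  # 0-based half-open
  starts <- GenomicRanges::start(gr) - 1L
  ends <- GenomicRanges::end(gr)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, character(1L))

  gene_idx <- which(type == "gene")
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  genes <- list()
  for (gi in gene_idx) {
    gid <- ids[[gi]]
    if (is.na(gid)) stop("gene feature without ID in ", path)
    if (!strand_chr[[gi]] %in% c("+", "-")) {
      stop("unknown strand symbol '", strand_chr[[gi]], "' for gene '", gid, "'")
    }
    mr <- mrna_idx[parents[mrna_idx] == gid]
    if (length(mr) == 0L) {
      # gene with exon/CDS children directly attached
      tid <- gid
    } else {
      if (length(mr) > 1L) {
        warning("gene '", gid, "' has ", length(mr),
                " mRNAs; using the first listed (", ids[[mr[1L]]], ")")
      }
      tid <- ids[[mr[1L]]]
    }
    ex <- which(type == "exon" & parents == tid)
    cd <- which(type == "CDS" & parents == tid)
    if (length(cd) == 0L) stop("gene '", gid, "' has no CDS features")
    exm <- if (length(ex) > 0L) {
      cbind(starts[ex], ends[ex])
    } else {
      cbind(starts[cd], ends[cd])
    }
    cdm <- cbind(starts[cd], ends[cd])
    genes[[gid]] <- gene_model(gid, chroms[[gi]], strand_chr[[gi]], exm, cdm)
  }
  if (length(genes) == 0L) stop("no gene features found in ", path)

  header <- readLines(path, n = 200L)
  region <- grep("^##sequence-region", header, value = TRUE)
  if (length(region) > 0L) {
    parts <- strsplit(trimws(region), "[[:space:]]+")
    lens <- vapply(parts, function(p) as.numeric(p[[4L]]), numeric(1L))
    names(lens) <- vapply(parts, function(p) p[[2L]], character(1L))
  } else {
    sl <- tapply(ends, chroms, max)
    lens <- as.numeric(sl)
    names(lens) <- names(sl)
  }
  annotation(genes, lens)
}

#' Write an annotation to GFF3
#'
#' Emits gene, mRNA, exon and CDS features (with CDS phase) through
#' [rtracklayer::export()]; internal 0-based half-open coordinates are
#' converted back to GFF3 1-based inclusive. Reading the file back with
#' [read_gff3()] reproduces identical internal coordinates.
#'
#' @param ann An [annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(ann, path) {
  rows <- list()
  for (g in ann$genes) {
    gid <- g$gene_id
    tid <- paste0(gid, ".t1")
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chromosome, start = gene_start(g) + 1L, end = gene_end(g),
      strand = g$strand, type = c("gene", "mRNA"),
      ID = c(gid, tid), Parent = c(NA, gid), phase = NA_integer_,
      stringsAsFactors = FALSE)
    ex <- g$exons
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chromosome, start = ex[, 1L] + 1L, end = ex[, 2L],
      strand = g$strand, type = "exon",
      ID = NA, Parent = tid, phase = NA_integer_, stringsAsFactors = FALSE)
    cd <- g$cds_segments
    # phase = (3 - cumulative coding length upstream mod 3) mod 3,
    # in transcription order
    ord <- if (g$strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
    lens <- cd[ord, 2L] - cd[ord, 1L]
    upstream <- cumsum(c(0L, lens[-length(lens)]))
    phase_tx <- (3L - upstream %% 3L) %% 3L
    phase <- integer(nrow(cd))
    phase[ord] <- phase_tx
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chromosome, start = cd[, 1L] + 1L, end = cd[, 2L],
      strand = g$strand, type = "CDS",
      ID = NA, Parent = tid, phase = phase, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  gr$source <- "iqdfam"
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- IRanges::CharacterList(lapply(df$Parent, function(p) {
    if (is.na(p)) character(0) else p
  }))
  gr$phase <- df$phase
  lens <- ann$chromosome_lengths
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  # make chromosome lengths round-trip via ##sequence-region directives
  lines <- readLines(path)
  pragmas <- sprintf("##sequence-region %s 1 %d", names(lens),
                     as.integer(lens))
  writeLines(c(lines[1L], pragmas, lines[-1L]), path)
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param x DNA character string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract the coding sequence of a gene from its chromosome sequence
#'
#' Concatenates the CDS segments in transcription order and
#' reverse-complements the result for minus-strand genes, returning the
#' mRNA-oriented 5'->3' coding sequence.
#'
#' @param gene A [gene_model()].
#' @param genome A DNA [seq_record()] whose `id` matches `gene$chromosome`.
#' @return A DNA `seq_record` named `<gene_id>_cds`.
#' @export
extract_cds <- function(gene, genome) {
  if (gene$chromosome != genome$id) {
    stop("gene '", gene$gene_id, "' is on '", gene$chromosome,
         "' but genome record is '", genome$id, "'")
  }
  n <- seq_length(genome)
  cd <- gene$cds_segments
  if (any(cd[, 2L] > n)) {
    stop("CDS segment of gene '", gene$gene_id,
         "' extends beyond the end of sequence '", genome$id, "' (", n, " bp)")
  }
  parts <- vapply(seq_len(nrow(cd)), function(i) {
    substr(genome$sequence, cd[i, 1L] + 1L, cd[i, 2L])
  }, character(1L))
  cds <- paste(parts, collapse = "")
  if (gene$strand == "-") cds <- revcomp(cds)
  seq_record(paste0(gene$gene_id, "_cds"), cds, "dna")
}

#' Translate a coding sequence
#'
#' Standard genetic code; a trailing stop codon is trimmed. Internal stop
#' codons are an error.
#'
#' @param cds A DNA `seq_record` or character string, length divisible by 3.
#' @param trim_stop Drop a trailing stop codon (default `TRUE`).
#' @return Protein character string.
#' @export
translate_cds <- function(cds, trim_stop = TRUE) {
  s <- if (inherits(cds, "seq_record")) cds$sequence else toupper(cds)
  if (nchar(s) %% 3L != 0L) {
    stop("CDS length (", nchar(s), ") is not divisible by 3")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           no.init.codon = TRUE))
  if (trim_stop && substring(aa, nchar(aa)) == "*") {
    aa <- substr(aa, 1L, nchar(aa) - 1L)
  }
  if (grepl("\\*", aa)) stop("internal stop codon in CDS")
  aa
}
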