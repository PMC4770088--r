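# DNA construct model: sequences, CpG sites, modification placement and
# cyclization-construct arithmetic.
#
# Conventions (used in every I/O header of this package):
#   * coordinates are 1-based and inclusive;
#   * the top strand is written 5'->3';
#   * bottom-strand positions are indexed along the bottom strand 5'->3', so
#     bottom position b pairs with top position L - b + 1;
#   * modification annotations are metadata carried next to a plain ACGT
#     sequence (no alternate alphabet letters), so FASTA round trips stay
#     standard-compliant; modified positions travel in a sidecar TSV.

MOD_TYPES <- c("5mC", "5hmC", "5fC", "5caC")
CONDITIONS <- c("unmodified", MOD_TYPES)

validate_sequence <- function(bases) {
  if (!is.character(bases) || length(bases) != 1L || is.na(bases)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  s <- toupper(bases)
  if (nchar(s) == 0L) stop("sequence must be nonempty", call. = FALSE)
  if (grepl("[^ACGT]", s)) {
    bad <- regmatches(s, regexpr("[^ACGT]", s))
    stop("sequence may contain only A, C, G, T (found '", bad, "')",
         call. = FALSE)
  }
  s
}

#' Reverse complement of a DNA sequence
#'
#' @param bases Single character string over `A`, `C`, `G`, `T`.
#' @return The reverse complement, 5'->3'.
#' @export
#' @examples
#' reverse_complement("ACCG")
reverse_complement <- function(bases) {
  s <- validate_sequence(bases)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' Find CpG dinucleotide steps on the top strand
#'
#' Exhaustive scan for 5'-CG-3' dinucleotides. A CpG step is its own reverse
#' complement as a duplex step, so the same physical steps are found on
#' either strand (reflected through `L - p`).
#'
#' @param bases Top-strand sequence, 5'->3'.
#' @return Sorted integer vector of 1-based start positions `p` with
#'   `bases[p] == "C"` and `bases[p + 1] == "G"`; empty if none.
#' @export
#' @examples
#' find_cpg_sites("CGCG")
find_cpg_sites <- function(bases) {
  s <- validate_sequence(bases)
  if (nchar(s) < 2L) return(integer(0))
  # CG cannot overlap itself, so a non-overlapping fixed scan is exhaustive
  m <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Interior CpG steps of a sequence
#'
#' CpG steps whose +/- 3 bp neighbourhood lies entirely inside the sequence,
#' i.e. start positions `p` with `4 <= p <= L - 4`. These are the default
#' sites at which modifications are placed (terminal CG steps excluded).
#'
#' @inheritParams find_cpg_sites
#' @return Integer vector of step start positions.
#' @export
interior_cpg_steps <- function(bases) {
  s <- validate_sequence(bases)
  p <- find_cpg_sites(s)
  p[p >= 4L & p <= nchar(s) - 4L]
}

validate_annotations <- function(ann, top, bottom) {
  need <- c("position", "strand", "mod_type")
  if (!is.data.frame(ann) || !all(need %in% names(ann))) {
    stop("annotations must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ann <- ann[, need, drop = FALSE]
  ann$position <- as.integer(ann$position)
  ann$strand <- as.character(ann$strand)
  ann$mod_type <- as.character(ann$mod_type)
  L <- nchar(top)
  if (any(!ann$strand %in% c("top", "bottom"))) {
    stop("annotation strand must be 'top' or 'bottom'", call. = FALSE)
  }
  if (any(!ann$mod_type %in% MOD_TYPES)) {
    stop("mod_type must be one of ", paste(MOD_TYPES, collapse = ", "),
         call. = FALSE)
  }
  if (any(ann$position < 1L | ann$position > L)) {
    stop("annotation position out of range 1..", L, call. = FALSE)
  }
  for (i in seq_len(nrow(ann))) {
    s <- if (ann$strand[i] == "top") top else bottom
    b <- substr(s, ann$position[i], ann$position[i])
    if (b != "C") {
      stop("annotated base at ", ann$strand[i], " position ",
           ann$position[i], " is ", b, ", not C", call. = FALSE)
    }
  }
  if (anyDuplicated(ann[, c("position", "strand")])) {
    stop("duplicate (position, strand) annotation", call. = FALSE)
  }
  ann <- ann[order(ann$strand, ann$position), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Double-stranded DNA with cytosine-modification annotations
#'
#' The bottom strand is derived as the exact reverse complement of the top
#' strand. Annotations mark cytosines carrying one of the four modifications
#' (5mC, 5hmC, 5fC, 5caC); every annotated base must be a C on its strand.
#'
#' @param top Top-strand sequence, 5'->3'.
#' @param annotations Optional data.frame with columns `position` (1-based,
#'   along the annotated strand 5'->3'), `strand` (`"top"`/`"bottom"`) and
#'   `mod_type`.
#' @return An object of class `modified_duplex` with elements `top`,
#'   `bottom`, `length` and `annotations`.
#' @export
#' @examples
#' d <- modified_duplex("AACGTT")
#' d$bottom
modified_duplex <- function(top, annotations = NULL) {
  top <- validate_sequence(top)
  bottom <- reverse_complement(top)
  if (is.null(annotations)) {
    annotations <- data.frame(position = integer(0), strand = character(0),
                              mod_type = character(0))
  }
  annotations <- validate_annotations(annotations, top, bottom)
  structure(list(top = top, bottom = bottom, length = nchar(top),
                 annotations = annotations),
            class = "modified_duplex")
}

#' @export
print.modified_duplex <- function(x, ...) {
  cat("modified_duplex:", x$length, "bp,",
      nrow(x$annotations), "modified cytosine(s)\n")
  cat("  top   : 5'-", x$top, "-3'\n", sep = "")
  cat("  bottom: 5'-", x$bottom, "-3'\n", sep = "")
  invisible(x)
}

#' Place cytosine modifications at CpG steps
#'
#' With `both_strands = TRUE` (the default) each CpG step contributes two
#' modified cytosines: the top-strand C at `p` and the bottom-strand C of the
#' complementary CpG (bottom position `L - p`), so `n` steps yield `2 n`
#' annotations. Base letters are never changed, only annotations are added.
#'
#' @param duplex A [modified_duplex()].
#' @param cpg_steps Integer vector of CpG step start positions on the top
#'   strand; each must satisfy `top[p] == "C"`, `top[p + 1] == "G"`.
#' @param mod_type One of `"5mC"`, `"5hmC"`, `"5fC"`, `"5caC"`.
#' @param both_strands Annotate both cytosines of each step?
#' @return A new `modified_duplex` carrying the added annotations.
#' @export
#' @examples
#' d <- modified_duplex("AACGTT")
#' apply_modifications(d, 3L, "5mC")$annotations
apply_modifications <- function(duplex, cpg_steps, mod_type,
                                both_strands = TRUE) {
  stopifnot(inherits(duplex, "modified_duplex"))
  mod_type <- match.arg(mod_type, MOD_TYPES)
  cpg_steps <- as.integer(cpg_steps)
  L <- duplex$length
  for (p in cpg_steps) {
    if (p < 1L || p >= L ||
        substr(duplex$top, p, p) != "C" ||
        substr(duplex$top, p + 1L, p + 1L) != "G") {
      stop("position ", p, " is not the start of a CpG step on the top strand",
           call. = FALSE)
    }
  }
  if (length(cpg_steps) == 0L) return(duplex)
  new_ann <- data.frame(position = cpg_steps, strand = "top",
                        mod_type = mod_type)
  if (both_strands && length(cpg_steps)) {
    new_ann <- rbind(new_ann,
                     data.frame(position = L - cpg_steps, strand = "bottom",
                                mod_type = mod_type))
  }
  modified_duplex(duplex$top, rbind(duplex$annotations, new_ann))
}

#' Cyclization construct geometry
#'
#' A linear duplex terminated by two complementary 5' overhangs of equal
#' length; on annealing the overhangs pair with each other, so the closed
#' loop circumference is `duplex_length + overhang_length` (the overhang
#' length counted once).
#'
#' @param duplex_length Duplex length in bp (> 0).
#' @param overhang_length Length of each 5' overhang in nt (>= 0).
#' @param label_positions Optional named integer vector of label positions
#'   (donor/acceptor/biotin), metadata only.
#' @return Object of class `cyclization_construct`.
#' @export
#' @examples
#' loop_circumference(cyclization_construct(80, 10))
cyclization_construct <- function(duplex_length, overhang_length,
                                  label_positions = NULL) {
  duplex_length <- as.numeric(duplex_length)
  overhang_length <- as.numeric(overhang_length)
  if (length(duplex_length) != 1L || !is.finite(duplex_length) ||
      duplex_length <= 0) {
    stop("duplex_length must be a positive number of bp", call. = FALSE)
  }
  if (length(overhang_length) != 1L || !is.finite(overhang_length) ||
      overhang_length < 0) {
    stop("overhang_length must be >= 0", call. = FALSE)
  }
  structure(list(duplex_length = duplex_length,
                 overhang_length = overhang_length,
                 label_positions = label_positions),
            class = "cyclization_construct")
}

#' Circumference of the closed loop
#'
#' @param construct A [cyclization_construct()].
#' @return Loop circumference in bp: `duplex_length + overhang_length`.
#' @export
loop_circumference <- function(construct) {
  stopifnot(inherits(construct, "cyclization_construct"))
  if (construct$duplex_length <= 0 || construct$overhang_length < 0) {
    stop("invalid construct dimensions", call. = FALSE)
  }
  construct$duplex_length + construct$overhang_length
}

#' Modification density of a duplex
#'
#' Percentage of modified bases among all bases of the duplex, both strands
#' counted: `100 * n_modified / (2 * duplex_length)`. The value is returned
#' unrounded; round only for display.
#'
#' @param duplex_length Duplex length in bp (> 0).
#' @param n_modified Number of modified bases (0 .. `2 * duplex_length`).
#' @return Density in percent.
#' @export
#' @examples
#' round(modification_density(147, 2), 2)  # 0.68
modification_density <- function(duplex_length, n_modified) {
  if (!is.finite(duplex_length) || duplex_length <= 0) {
    stop("duplex_length must be positive", call. = FALSE)
  }
  if (!is.finite(n_modified) || n_modified < 0 ||
      n_modified > 2 * duplex_length) {
    stop("n_modified must lie in 0 .. 2 * duplex_length", call. = FALSE)
  }
  100 * n_modified / (2 * duplex_length)
}

#' Central 70-mer of the cyclization construct
#'
#' Top-strand sequence of the central 70-bp region of the cyclization
#' construct, carrying four interior CpG steps (starts 22, 28, 34, 46) plus
#' a terminal CG at 69.
#'
#' @return Character string of length 70.
#' @export
cyclization_core_70mer <- function() {
  paste0("TACCTCAATATAGACTCCCTCCGGTGCCGAGGCCGCTCAATTGGTCGTAGG",
         "ACTATCCTCACCTCCACCG")
}

# ---- I/O ------------------------------------------------------------------

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (single- or multi-record).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write the modification sidecar TSV
#'
#' Columns `position` (1-based along the annotated strand, 5'->3'),
#' `strand`, `mod_type`; header line mandatory.
#'
#' @param duplex A [modified_duplex()].
#' @param path Output TSV.
#' @export
write_modifications <- function(duplex, path) {
  stopifnot(inherits(duplex, "modified_duplex"))
  utils::write.table(duplex$annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a modification sidecar TSV
#'
#' @param path TSV with mandatory header `position`, `strand`, `mod_type`.
#' @return data.frame of annotations.
#' @export
read_modifications <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("integer", "character", "character"))
  need <- c("position", "strand", "mod_type")
  if (!all(need %in% names(ann))) {
    stop("modification TSV must have header columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ann
}
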