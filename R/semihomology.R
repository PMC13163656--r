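#' Codon table for semihomologous position typing
#'
#' Wraps an NCBI genetic-code table (via [Biostrings::getGeneticCode()]) as a
#' map from amino-acid letter to its set of RNA codons.  Table 1 is the
#' universal code; table 2 (vertebrate mitochondrial) is relevant because
#' cytochrome b and COI are mitochondrial loci.  The choice can change the
#' transition/transversion split of a pair, never whether it is homologous.
#'
#' @param table_id `"1"` (universal, default) or `"2"` (vertebrate
#'   mitochondrial); any identifier accepted by
#'   [Biostrings::getGeneticCode()] works.
#' @return Object of class `codon_table` with `table_id`, `codons_of`
#'   (named list of RNA codon character vectors per amino acid),
#'   `stop_codons`, and `sense_codons`.
#' @export
codon_table <- function(table_id = "1") {
  gc <- Biostrings::getGeneticCode(as.character(table_id))
  codons <- chartr("T", "U", names(gc))
  stop_codons <- codons[gc == "*"]
  aa <- gc[gc != "*"]
  codons_of <- split(codons[gc != "*"], aa)
  structure(list(table_id = as.character(table_id),
                 codons_of = codons_of,
                 stop_codons = stop_codons,
                 sense_codons = setNames(unname(aa), codons[gc != "*"])),
            class = "codon_table")
}

#' Is a base substitution a transition?
#'
#' Transitions are purine-purine (`A`/`G`) or pyrimidine-pyrimidine (`C`/`U`)
#' interchanges; everything else among the four RNA bases is a transversion.
#'
#' @param base1,base2 Distinct single RNA bases in `A`, `C`, `G`, `U`.
#' @return `TRUE` for a transition, `FALSE` for a transversion.
#' @examples
#' is_transition("A", "G")  # TRUE
#' is_transition("A", "C")  # FALSE
#' @export
is_transition <- function(base1, base2) {
  bases <- c("A", "C", "G", "U")
  if (!(base1 %in% bases) || !(base2 %in% bases))
    stop("bases must be RNA letters A, C, G, U", call. = FALSE)
  if (base1 == base2)
    stop("bases must differ to be typed", call. = FALSE)
  purine <- c("A", "G")
  (base1 %in% purine) == (base2 %in% purine)
}

codon_hamming <- function(c1, c2) {
  sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
}

# standard one-letter amino acids that have codons in every shipped table
standard_aas <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Minimum point mutations between two amino acids
#'
#' Minimum Hamming distance over all codon pairs drawn from the two amino
#' acids' codon sets; 0 iff the amino acids are equal.
#'
#' @param aa1,aa2 Single amino-acid letters.
#' @param table A [codon_table()].
#' @return Integer in `0:3`, or `NA_integer_` ("uncodable") when either
#'   letter has no codons in the table (pads, ambiguity codes).
#' @export
min_point_mutations <- function(aa1, aa2, table = codon_table()) {
  c1 <- table$codons_of[[toupper(aa1)]]
  c2 <- table$codons_of[[toupper(aa2)]]
  if (is.null(c1) || is.null(c2)) return(NA_integer_)
  best <- 3L
  for (x in c1) for (y in c2) {
    d <- codon_hamming(x, y)
    if (d < best) best <- d
    if (best == 0L) return(0L)
  }
  best
}

# For a residue pair at codon distance 1: which single-site substitution
# types occur among the distance-1 codon pairs?
dist1_sub_types <- function(c1, c2) {
  has_ts <- FALSE; has_tv <- FALSE
  for (x in c1) {
    xs <- strsplit(x, "")[[1]]
    for (y in c2) {
      ys <- strsplit(y, "")[[1]]
      diff <- which(xs != ys)
      if (length(diff) == 1L) {
        if (is_transition(xs[diff], ys[diff])) has_ts <- TRUE else has_tv <- TRUE
      }
    }
  }
  c(ts = has_ts, tv = has_tv)
}

#' Classify one aligned amino-acid position
#'
#' Positions are homologous (`R`, identical standard amino acids),
#' transition-type semihomologous (`#`, some codon pair of the two amino
#' acids differs by exactly one transition), transversion-type
#' semihomologous (`$`, one transversion), or other (`-`, two or three point
#' mutations needed, or either side is a pad/uncodable symbol).  When a pair
#' admits distance-1 codon pairs of both types, `tie_policy` decides which
#' symbol wins; the default favours transitions, which dominate in molecular
#' evolution.
#'
#' @param aa1,aa2 Single residue letters (pads allowed).
#' @param table A [codon_table()].
#' @param tie_policy `"transition"` (default) or `"transversion"`.
#' @return One of `"R"`, `"#"`, `"$"`, `"-"`.
#' @examples
#' classify_pair("D", "N")  # "#"
#' classify_pair("D", "E")  # "$"
#' @export
classify_pair <- function(aa1, aa2, table = codon_table(),
                          tie_policy = c("transition", "transversion")) {
  tie_policy <- match.arg(tie_policy)
  aa1 <- toupper(aa1); aa2 <- toupper(aa2)
  c1 <- table$codons_of[[aa1]]
  c2 <- table$codons_of[[aa2]]
  if (is.null(c1) || is.null(c2)) return("-")
  if (aa1 == aa2) return("R")
  d <- min_point_mutations(aa1, aa2, table)
  if (d != 1L) return("-")
  types <- dist1_sub_types(c1, c2)
  if (types["ts"] && types["tv"])
    return(if (tie_policy == "transition") "#" else "$")
  if (types["ts"]) "#" else "$"
}

#' Full position-class matrix over the residue alphabet
#'
#' @inheritParams classify_pair
#' @param alphabet A [residue_alphabet()].
#' @return Symmetric character matrix over the alphabet symbols with entries
#'   in `R`, `#`, `$`, `-`; the standard-residue diagonal is all `R`.
#' @export
pair_class_table <- function(table = codon_table(),
                             tie_policy = c("transition", "transversion"),
                             alphabet = residue_alphabet()) {
  tie_policy <- match.arg(tie_policy)
  syms <- alphabet$symbols
  m <- matrix("-", length(syms), length(syms), dimnames = list(syms, syms))
  for (i in seq_along(syms)) for (j in i:length(syms)) {
    cl <- classify_pair(syms[i], syms[j], table, tie_policy)
    m[i, j] <- cl; m[j, i] <- cl
  }
  m
}

#' Count position classes between two equal-length sequences
#'
#' Tallies `R`, `#`, `$` and `-` positions over an aligned (reference-fitted)
#' sequence pair; the four counts always sum to the compared length, so
#' padded tails land in the `-` bucket.
#'
#' @param seqA,seqB Equal-length residue strings.
#' @inheritParams classify_pair
#' @param detail If `TRUE`, attach a per-position data frame
#'   (`position`, `aaA`, `aaB`, `class`) as attribute `"positions"`.
#' @return Object of class `position_class_counts`: list with `r`, `ts`,
#'   `tv`, `other`, `total`.
#' @export
count_positions <- function(seqA, seqB, table = codon_table(),
                            tie_policy = c("transition", "transversion"),
                            detail = FALSE) {
  tie_policy <- match.arg(tie_policy)
  if (nchar(seqA) != nchar(seqB))
    stop(sprintf("sequence lengths differ (%d vs %d); fit both to the reference first",
                 nchar(seqA), nchar(seqB)), call. = FALSE)
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  lut <- pair_class_lut(table, tie_policy)
  cls <- lut[cbind(a, b)]
  counts <- structure(list(r = sum(cls == "R"), ts = sum(cls == "#"),
                           tv = sum(cls == "$"), other = sum(cls == "-"),
                           total = length(cls)),
                      class = "position_class_counts")
  if (detail)
    attr(counts, "positions") <- data.frame(position = seq_along(cls),
                                            aaA = a, aaB = b, class = cls,
                                            stringsAsFactors = FALSE)
  counts
}

# memoised class matrix per (table, tie policy)
pair_class_lut <- local({
  cache <- new.env(parent = emptyenv())
  function(table, tie_policy) {
    key <- paste(table$table_id, tie_policy, sep = "/")
    if (is.null(cache[[key]]))
      cache[[key]] <- pair_class_table(table, tie_policy)
    cache[[key]]
  }
})

#' @export
print.position_class_counts <- function(x, ...) {
  cat(format_counts(x), "\n")
  invisible(x)
}

#' Bracket rendering of position-class counts
#'
#' Formats counts in the `[R/#/$/-]` layout used in recognition reports,
#' e.g. `"[862/24/3/4]"`.
#'
#' @param counts A `position_class_counts`.
#' @return A string.
#' @export
format_counts <- function(counts) {
  sprintf("[%d/%d/%d/%d]", counts$r, counts$ts, counts$tv, counts$other)
}
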