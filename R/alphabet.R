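#' Residue alphabet with five-bit codes
#'
#' The image encoding assigns each residue letter a five-bit binary code:
#' `A` = `00001`, `B` = `00010`, `C` = `00011`, `D` = `00100` and so on in
#' alphabetic order up to `Z` = `11010`; the padding character `-` is
#' `00000`.  The alphabet deliberately covers all 26 letters so that
#' ambiguity codes (B, J, O, U, X, Z) occurring in downloaded protein
#' records encode without error.
#'
#' @return An object of class `residue_alphabet` with components `symbols`
#'   (the 27 characters, `-` first), `code_of` (named integer vector mapping
#'   symbol to its integer code in `[0, 26]`) and `pad_symbol`.
#' @examples
#' ab <- residue_alphabet()
#' ab$code_of[["A"]]  # 1
#' @export
residue_alphabet <- function() {
  symbols <- c("-", LETTERS)
  structure(
    list(symbols = symbols,
         code_of = setNames(0:26, symbols),
         pad_symbol = "-"),
    class = "residue_alphabet")
}

#' Five-bit code of a residue letter
#'
#' @param symbol Single character, a letter `A`-`Z` (case-insensitive) or the
#'   pad `-`.
#' @param alphabet A [residue_alphabet()].
#' @param position Optional integer used in the error message when `symbol`
#'   is unknown (position within a sequence).
#' @return Integer vector of length 5 with elements in `{0, 1}`, most
#'   significant bit first (`A` gives `c(0, 0, 0, 0, 1)`).
#' @examples
#' residue_code("A")  # 0 0 0 0 1
#' residue_code("-")  # 0 0 0 0 0
#' @export
residue_code <- function(symbol, alphabet = residue_alphabet(),
                         position = NA_integer_) {
  stopifnot(is.character(symbol), length(symbol) == 1L, nchar(symbol) == 1L)
  symbol <- toupper(symbol)
  code <- alphabet$code_of[symbol]
  if (is.na(code)) {
    stop(sprintf("unknown residue symbol '%s'%s", symbol,
                 if (is.na(position)) "" else sprintf(" at position %d", position)),
         call. = FALSE)
  }
  as.integer(bitwAnd(bitwShiftR(code, 4:0), 1L))
}

# vectorised encoder: residue string -> 0/1 integer vector, 5 bits per residue
encode_residues <- function(seq, alphabet = residue_alphabet()) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- alphabet$code_of[chars]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf("unknown residue symbol '%s' at position %d", chars[bad], bad),
         call. = FALSE)
  }
  # vapply gives a 5 x n matrix (one column per residue); column-major
  # flattening yields the residue-major bit order
  as.integer(vapply(codes, function(k) bitwAnd(bitwShiftR(k, 4:0), 1L),
                    integer(5)))
}

decode_codes <- function(codes, alphabet = residue_alphabet()) {
  symbols <- alphabet$symbols[match(codes, alphabet$code_of)]
  if (anyNA(symbols)) {
    bad <- which(is.na(symbols))[1L]
    stop(sprintf("unknown 5-bit code %d at residue %d", codes[bad], bad),
         call. = FALSE)
  }
  paste(symbols, collapse = "")
}

#' Reference lengths for image alignment
#'
#' Sequences are end-padded with `-` or end-truncated to fixed reference
#' lengths before encoding, so all images in a panel have equal size.  The
#' defaults are the human cytochrome b (380 residues) and COI (513 residues)
#' lengths; synthetic panels use shorter references.
#'
#' @param cytb_len,coi_len Positive residue counts.
#' @return Object of class `reference_lengths`.
#' @export
reference_lengths <- function(cytb_len = 380L, coi_len = 513L) {
  cytb_len <- as.integer(cytb_len); coi_len <- as.integer(coi_len)
  stopifnot(length(cytb_len) == 1L, length(coi_len) == 1L,
            cytb_len > 0L, coi_len > 0L)
  structure(list(cytb_len = cytb_len, coi_len = coi_len),
            class = "reference_lengths")
}

#' Fit a sequence to a reference length
#'
#' Shorter sequences are end-padded with `-`; longer ones are end-truncated.
#' No alignment beyond this is performed.
#'
#' @param seq Residue string.
#' @param target_len Positive integer.
#' @return A string with exactly `target_len` residues.
#' @examples
#' fit_to_reference("MA", 4)    # "MA--"
#' fit_to_reference("MACD", 3)  # "MAC"
#' @export
fit_to_reference <- function(seq, target_len) {
  stopifnot(is.character(seq), length(seq) == 1L)
  target_len <- as.integer(target_len)
  stopifnot(target_len > 0L)
  n <- nchar(seq)
  if (n >= target_len) return(substr(seq, 1L, target_len))
  paste0(seq, strrep("-", target_len - n))
}

#' Construct an organism record
#'
#' @param common_name,latin_name Organism names.
#' @param cytb_seq,coi_seq Amino-acid strings (uppercased on construction).
#' @return Object of class `organism_record`.
#' @export
organism_record <- function(common_name, latin_name, cytb_seq, coi_seq) {
  stopifnot(nzchar(cytb_seq), nzchar(coi_seq))
  ab <- residue_alphabet()
  for (s in c(cytb_seq, coi_seq)) encode_residues(s, ab)  # validates symbols
  structure(list(common_name = common_name, latin_name = latin_name,
                 cytb_seq = toupper(cytb_seq), coi_seq = toupper(coi_seq)),
            class = "organism_record")
}

# concatenated, reference-fitted residue string for a record in a given mode
fitted_sequence <- function(record, ref = reference_lengths(),
                            mode = c("concat", "cytb", "coi")) {
  mode <- match.arg(mode)
  switch(mode,
         concat = paste0(fit_to_reference(record$cytb_seq, ref$cytb_len),
                         fit_to_reference(record$coi_seq, ref$coi_len)),
         cytb   = fit_to_reference(record$cytb_seq, ref$cytb_len),
         coi    = fit_to_reference(record$coi_seq, ref$coi_len))
}

#' Build a genetic image
#'
#' Fits the record's sequences to the reference lengths (cytochrome b first,
#' then COI for `concat` mode), then encodes residue-by-residue into a
#' five-bit-per-residue bit vector.  With the default reference lengths the
#' bit lengths are 4465 (`concat`, 5 x (380 + 513)), 1900 (`cytb`) and 2565
#' (`coi`).
#'
#' @param record An [organism_record()] (or a list with the same fields).
#' @param ref A [reference_lengths()].
#' @param mode One of `"concat"`, `"cytb"`, `"coi"`.
#' @param alphabet A [residue_alphabet()].
#' @return Object of class `genetic_image` with fields `organism_id`, `mode`,
#'   `bits` (integer 0/1 vector) and `residue_len`.
#' @export
build_genetic_image <- function(record, ref = reference_lengths(),
                                mode = c("concat", "cytb", "coi"),
                                alphabet = residue_alphabet()) {
  mode <- match.arg(mode)
  seq <- fitted_sequence(record, ref, mode)
  bits <- encode_residues(seq, alphabet)
  structure(list(organism_id = record$latin_name, mode = mode, bits = bits,
                 residue_len = nchar(seq)),
            class = "genetic_image")
}

#' Decode a genetic image back to its residue string
#'
#' @param image A `genetic_image` (or any list with `bits`).
#' @param alphabet A [residue_alphabet()].
#' @return The residue string of length `residue_len`.
#' @export
decode_image <- function(image, alphabet = residue_alphabet()) {
  bits <- image$bits
  if (length(bits) %% 5L != 0L)
    stop("bit length not divisible by 5", call. = FALSE)
  m <- matrix(bits, nrow = 5L)
  codes <- as.integer(crossprod(m, 2L^(4:0)))
  decode_codes(codes, alphabet)
}

#' Default colour palette for image rendering
#'
#' One distinct colour per residue letter; the pad renders white.
#' @return Named character vector of hex colours over the 27 symbols.
#' @export
default_palette <- function() {
  ab <- residue_alphabet()
  cols <- c("#FFFFFF", grDevices::hcl(h = seq(15, 375, length.out = 27)[-27],
                                      c = 80, l = 60))
  setNames(cols, ab$symbols)
}

#' Render a genetic image as a PNG raster
#'
#' Purely a debugging/visualisation aid: one coloured cell per residue laid
#' out row-major on a `rows x cols` grid, written deterministically so that
#' identical sequences give byte-identical files.
#'
#' @param image A `genetic_image`.
#' @param path Output PNG path.
#' @param palette Named colours per residue symbol (default
#'   [default_palette()]).
#' @param rows,cols Grid layout; `rows * cols` must be at least
#'   `residue_len`.  Defaults to a near-square grid.
#' @param cell Cell side length in pixels.
#' @return `path`, invisibly.
#' @export
render_image <- function(image, path, palette = default_palette(),
                         rows = NULL, cols = NULL, cell = 4L) {
  n <- image$residue_len
  if (is.null(cols)) cols <- ceiling(sqrt(n))
  if (is.null(rows)) rows <- ceiling(n / cols)
  if (rows * cols < n)
    stop(sprintf("layout %dx%d has fewer cells than %d residues",
                 rows, cols, n), call. = FALSE)
  seq <- decode_image(image)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cols_hex <- unname(palette[chars])
  if (anyNA(cols_hex)) stop("palette missing a symbol", call. = FALSE)
  grid <- rep("#FFFFFF", rows * cols)
  grid[seq_len(n)] <- cols_hex
  rgb <- grDevices::col2rgb(grid) / 255
  img <- array(0, dim = c(rows, cols, 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, ], nrow = rows, byrow = TRUE)
  if (cell > 1L) {
    big <- array(0, dim = c(rows * cell, cols * cell, 3))
    one <- matrix(1, cell, cell)
    for (ch in 1:3) big[, , ch] <- kronecker(img[, , ch], one)
    img <- big
  }
  png::writePNG(img, target = path)
  invisible(path)
}
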