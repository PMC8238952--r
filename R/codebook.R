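#' Construct an extended Hamming code
#'
#' Builds the extended (Hamming-plus-overall-parity) binary code of a
#' power-of-two length. The extended \eqn{[2^m, 2^m - m - 1]} code has minimum
#' pairwise Hamming distance 4, which permits correction of any single bit
#' error among codewords; its length-16 instance underlies the MERFISH barcode
#' scheme.
#'
#' @param n_bits Code length; one of 8, 16 or 32.
#' @return Integer matrix with one codeword per row and `n_bits` columns of
#'   0/1 values. For length 16 the matrix has \eqn{2^{11} = 2048} rows.
#' @examples
#' code <- build_extended_hamming_code(8)
#' nrow(code)  # 16 codewords
#' @export
build_extended_hamming_code <- function(n_bits) {
  if (!is.numeric(n_bits) || length(n_bits) != 1 || !n_bits %in% c(8L, 16L, 32L)) {
    stop("'n_bits' must be one of 8, 16, 32")
  }
  n_bits <- as.integer(n_bits)
  m <- as.integer(log2(n_bits))
  n_ham <- n_bits - 1L          # classical Hamming length 2^m - 1
  k <- n_ham - m                # message bits
  pow2 <- 2L^(0:(m - 1L))       # parity positions (1-based) in the Hamming code
  data_pos <- setdiff(seq_len(n_ham), pow2)

  n_words <- 2L^k
  msg <- 0:(n_words - 1L)
  # message bit b (0-based) of every word
  data_bits <- sapply(seq_len(k) - 1L, function(b) bitwAnd(bitwShiftR(msg, b), 1L))
  code <- matrix(0L, n_words, n_ham)
  code[, data_pos] <- data_bits
  # parity bit at position 2^j checks all positions whose index has bit j set
  for (j in seq_len(m) - 1L) {
    covered <- data_pos[bitwAnd(data_pos, 2L^j) > 0L]
    code[, 2L^j] <- as.integer(rowSums(code[, covered, drop = FALSE]) %% 2L)
  }
  cbind(code, as.integer(rowSums(code) %% 2L))
}

#' Build a Hamming-distance-4 constant-weight barcode codebook
#'
#' Takes the Hamming-weight-4 codewords of the length-16 extended Hamming code
#' (140 words in total) and assigns them to genes, optionally reserving some
#' as unused "blank" barcodes for false-positive estimation. Assignment order
#' is a deterministic seeded permutation of the available codewords.
#'
#' @param gene_names Character vector of gene names.
#' @param n_blanks Number of blank barcodes to reserve (default 0).
#' @param n_bits Barcode length (default 16).
#' @param seed Integer seed controlling the gene-to-barcode permutation.
#' @return A `mf_codebook`: data frame with columns `name`, `barcode`
#'   (bit string such as `"0100100000101000"`), and `is_blank`.
#' @examples
#' cb <- build_mhd4_codebook(c("Mecom", "Kit"), n_blanks = 2)
#' cb$barcode
#' @export
build_mhd4_codebook <- function(gene_names, n_blanks = 0L, n_bits = 16L, seed = 1L) {
  stopifnot(is.character(gene_names) || length(gene_names) == 0)
  gene_names <- as.character(gene_names)
  if (anyDuplicated(gene_names)) stop("duplicated gene names")
  code <- build_extended_hamming_code(n_bits)
  w4 <- code[rowSums(code) == 4L, , drop = FALSE]
  need <- length(gene_names) + n_blanks
  if (need > nrow(w4)) {
    stop(sprintf("requested %d barcodes but only %d weight-4 codewords exist",
                 need, nrow(w4)))
  }
  ord <- with_local_seed(seed, sample.int(nrow(w4)))
  picked <- w4[ord[seq_len(need)], , drop = FALSE]
  names_all <- c(gene_names, if (n_blanks > 0) sprintf("Blank-%d", seq_len(n_blanks)))
  cb <- data.frame(
    name = if (need > 0) names_all else character(0),
    barcode = if (need > 0) apply(picked, 1, paste0, collapse = "") else character(0),
    is_blank = rep(c(FALSE, TRUE), c(length(gene_names), n_blanks)),
    stringsAsFactors = FALSE
  )
  class(cb) <- c("mf_codebook", "data.frame")
  validate_codebook(cb)
  cb
}

#' @export
print.mf_codebook <- function(x, ...) {
  cat(sprintf("MERFISH codebook: %d genes, %d blanks, %d-bit barcodes\n",
              sum(!x$is_blank), sum(x$is_blank),
              if (nrow(x)) nchar(x$barcode[1]) else NA_integer_))
  invisible(x)
}

validate_codebook <- function(cb) {
  if (nrow(cb) == 0) return(invisible(cb))
  B <- barcode_matrix(cb)
  if (any(nchar(cb$barcode) != ncol(B))) stop("barcodes of unequal length")
  if (any(rowSums(B) != 4L)) stop("all barcodes must have Hamming weight 4")
  if (anyDuplicated(cb$barcode)) stop("duplicated barcodes")
  if (anyDuplicated(cb$name)) stop("duplicated entry names")
  if (nrow(B) > 1) {
    d <- hamming_dist_matrix(B, B)
    diag(d) <- Inf
    if (min(d) < 4) stop("codebook violates minimum Hamming distance 4")
  }
  invisible(cb)
}

#' Bit matrix of a codebook
#'
#' @param cb A `mf_codebook`.
#' @return Integer matrix, one barcode per row, rownames the entry names.
#' @export
barcode_matrix <- function(cb) {
  if (nrow(cb) == 0) return(matrix(0L, 0, 16))
  B <- t(vapply(strsplit(cb$barcode, ""), function(x) as.integer(x),
                integer(nchar(cb$barcode[1]))))
  rownames(B) <- cb$name
  B
}

# pairwise Hamming distances between rows of two 0/1 matrices
hamming_dist_matrix <- function(A, B) {
  A %*% t(1 - B) + (1 - A) %*% t(B)
}

#' Decode a barcode bit vector against a codebook
#'
#' Matches a (possibly corrupted) readout bit vector to the unique codebook
#' entry within `max_errors` bit flips. With a minimum-distance-4 code and
#' `max_errors = 1` the match, when it exists, is always unique.
#'
#' @param bit_vector Integer/logical vector of 16 bits.
#' @param codebook A `mf_codebook`.
#' @param max_errors Maximum correctable bit errors; must be < half the
#'   minimum distance, i.e. 0 or 1 here.
#' @return The matched entry name, or `NA_character_` if no entry lies within
#'   `max_errors`.
#' @export
decode_bits <- function(bit_vector, codebook, max_errors = 1L) {
  B <- barcode_matrix(codebook)
  if (length(bit_vector) != ncol(B) && nrow(B) > 0) {
    stop(sprintf("bit vector must have %d bits", ncol(B)))
  }
  if (max_errors >= 2) {
    stop("max_errors >= 2 is ambiguous for a minimum-distance-4 code")
  }
  decode_bit_rows(matrix(as.integer(bit_vector), nrow = 1), codebook, max_errors)
}

# Vectorised decoder: rows of `bits` are pixels/readouts; returns a character
# vector of entry names (NA where nothing is within max_errors).
decode_bit_rows <- function(bits, codebook, max_errors = 1L) {
  if (nrow(codebook) == 0) return(rep(NA_character_, nrow(bits)))
  B <- barcode_matrix(codebook)
  out <- rep(NA_character_, nrow(bits))
  if (nrow(bits) == 0) return(out)
  # only rows with weight within max_errors of 4 can possibly match
  w <- rowSums(bits)
  cand <- which(abs(w - 4L) <= max_errors)
  if (length(cand) == 0) return(out)
  d <- hamming_dist_matrix(bits[cand, , drop = FALSE], B)
  best <- max.col(-d, ties.method = "first")
  bestd <- d[cbind(seq_along(cand), best)]
  hit <- bestd <= max_errors
  out[cand[hit]] <- codebook$name[best[hit]]
  out
}

#' Read / write a codebook as JSON
#'
#' The on-disk format is a JSON array of objects with fields `name`,
#' `barcode` (bit string) and `is_blank`; invariants (weight 4, pairwise
#' distance >= 4, uniqueness) are validated on load.
#'
#' @param path File path.
#' @return `read_codebook` returns a validated `mf_codebook`.
#' @examples
#' cb <- read_codebook(system.file("extdata", "example_codebook.json",
#'                                 package = "merfishniche"))
#' sum(!cb$is_blank)
#' @export
read_codebook <- function(path) {
  df <- jsonlite::fromJSON(path)
  cb <- data.frame(name = as.character(df$name),
                   barcode = as.character(df$barcode),
                   is_blank = as.logical(df$is_blank),
                   stringsAsFactors = FALSE)
  class(cb) <- c("mf_codebook", "data.frame")
  validate_codebook(cb)
  cb
}

#' @rdname read_codebook
#' @param cb A `mf_codebook`.
#' @export
write_codebook <- function(cb, path) {
  jsonlite::write_json(as.data.frame(cb), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# run `expr` under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
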