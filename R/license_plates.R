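# Sequence-derived "license plate" identifiers.
#
# A plate has the form <prefix>-<length>-<payload>. The payload encodes the
# sequence itself: each nucleotide contributes two bits (A=00, C=01, G=10,
# T=11), the bit string is split into successive 5-bit groups (a trailing
# group of fewer than five bits is read as its own integer value), and each
# group indexes a fixed 32-symbol alphabet. The alphabet interleaves the 22
# letters that are not nucleotide codes (so a payload can never be misread
# as a sequence) with the digits 0-9 in every third slot. The mapping is a
# bijection: decoding a plate recovers the sequence exactly, so the
# identifier is stable across genome assemblies and annotation releases.

PLATE_ALPHABET <- strsplit("BD0EF1HI2JK3LM4NO5PQ6RS7UV8WX9YZ", "")[[1]]
PLATE_BASE_BITS <- c(A = 0L, C = 1L, G = 2L, T = 3L)

#' Encode DNA sequences as license plates
#'
#' Converts each sequence into its unique, assembly-independent identifier of
#' the form `prefix-length-payload`. Every distinct sequence maps to a
#' distinct plate and [decode_plate()] inverts the mapping exactly.
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T}`.
#' @param prefix Identifier prefix; `"iso"` marks miRNA isoforms.
#' @return Character vector of license plates, one per input sequence.
#' @examples
#' encode_plate("CCCATAAAGTAGAAAGCACT")
#' @seealso [decode_plate()], [plate_table()]
#' @export
encode_plate <- function(seq, prefix = "iso") {
  assert_dna(seq)
  stopifnot(is.character(prefix), length(prefix) == 1L, nzchar(prefix))
  vapply(seq, function(s) {
    n <- nchar(s)
    bases <- strsplit(s, "")[[1]]
    vals <- unname(PLATE_BASE_BITS[bases])
    bits <- as.vector(rbind(vals %/% 2L, vals %% 2L))
    n_sym <- ceiling(length(bits) / 5)
    payload <- vapply(seq_len(n_sym), function(i) {
      g <- bits[(5L * i - 4L):min(5L * i, length(bits))]
      v <- sum(g * 2L^(rev(seq_along(g)) - 1L))
      PLATE_ALPHABET[v + 1L]
    }, character(1))
    paste0(prefix, "-", n, "-", paste(payload, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Decode license plates back to DNA sequences
#'
#' Inverts [encode_plate()]: `decode_plate(encode_plate(s)) == s` for every
#' valid DNA sequence `s`. Malformed plates (unknown payload symbols, a
#' payload whose size disagrees with the length field, or trailing bits that
#' do not fit) raise an error.
#'
#' @param plate Character vector of plates of the form `prefix-length-payload`.
#' @return Character vector of DNA sequences.
#' @examples
#' decode_plate("iso-20-KQB3FBPI")
#' @export
decode_plate <- function(plate) {
  vapply(plate, function(p) {
    parts <- strsplit(p, "-", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed plate (expected prefix-length-payload): ", p,
           call. = FALSE)
    }
    len <- suppressWarnings(as.integer(parts[length(parts) - 1L]))
    payload <- parts[length(parts)]
    if (is.na(len) || len < 1L) {
      stop("malformed plate length field: ", p, call. = FALSE)
    }
    syms <- match(strsplit(payload, "")[[1]], PLATE_ALPHABET) - 1L
    if (anyNA(syms)) {
      stop("plate payload contains symbols outside the alphabet: ", p,
           call. = FALSE)
    }
    nbits <- 2L * len
    if (length(syms) != ceiling(nbits / 5)) {
      stop("plate payload size disagrees with its length field: ", p,
           call. = FALSE)
    }
    widths <- rep(5L, length(syms))
    last <- nbits - 5L * (length(syms) - 1L)
    widths[length(widths)] <- last
    if (any(syms >= 2L^widths)) {
      stop("plate payload encodes more bits than its length field allows: ",
           p, call. = FALSE)
    }
    bits <- unlist(lapply(seq_along(syms), function(i) {
      as.integer(intToBits(syms[i]))[widths[i]:1]
    }))
    vals <- 2L * bits[c(TRUE, FALSE)] + bits[c(FALSE, TRUE)]
    paste(names(PLATE_BASE_BITS)[vals + 1L], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Batch encode or decode plates for a sequence table
#'
#' Data-frame-first convenience wrapper: adds a `plate` column for a table of
#' sequences, or a `seq` column for a table of plates.
#'
#' @param data A data frame.
#' @param col Name of the column holding sequences (for `plate_table()`) or
#'   plates (for `unplate_table()`).
#' @param prefix Plate prefix passed to [encode_plate()].
#' @return The input as a tibble with the derived column appended.
#' @export
plate_table <- function(data, col = "seq", prefix = "iso") {
  as_tibble(data) |>
    mutate(plate = encode_plate(.data[[col]], prefix = prefix))
}

#' @rdname plate_table
#' @export
unplate_table <- function(data, col = "plate") {
  as_tibble(data) |>
    mutate(seq = decode_plate(.data[[col]]))
}
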