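DNA_BASES <- c("A", "C", "G", "T")
# Watson-Crick complement of the guide base (RNA U treated as T)
WC_COMP <- c(A = "T", C = "G", G = "C", T = "A")

canon_base <- function(x) {
  x <- toupper(x)
  x[x == "U"] <- "T"
  x
}

#' Encode a guide/target pairing sequence for the in vitro mode
#'
#' Reduces each gRNA--DNA position to a pairing class and one-hot encodes it
#' as an \code{L x 4} matrix: channel 1 marks a Watson-Crick complementary
#' (matched) pair; channels 2--4 mark the three mismatch classes, defined by
#' the cyclic offset of the observed target base from the complementary one
#' (offset 1, 2, 3 in A,C,G,T order). The class is a deterministic function
#' of the pair identity, complementary pairs always map to channel 1, and
#' the target is recoverable given the guide (\code{\link{decode_pairing}}).
#' This is the encoding consumed by the per-rate window convolutions of the
#' simulator-trained KINNs.
#'
#' @param guide,target equal-length sequences (strings or character vectors)
#'   over A,C,G,T/U; the guide is read as RNA or DNA indifferently.
#' @param L expected length (default 50); a length mismatch is an error.
#' @return \code{L x 4} binary matrix, columns
#'   \code{match}, \code{mm1}, \code{mm2}, \code{mm3}.
#' @export
encode_pairing <- function(guide, target, L = 50L) {
  g <- canon_base(seq_chars(guide)); t <- canon_base(seq_chars(target))
  if (length(g) != length(t))
    stop("guide and target must have equal length (got ",
         length(g), " and ", length(t), ")")
  if (length(g) != L)
    stop("sequence length ", length(g), " does not match L = ", L)
  bad <- !(g %in% DNA_BASES) | !(t %in% DNA_BASES)
  if (any(bad))
    stop("illegal character(s) at position(s): ",
         paste(which(bad), collapse = ", "))
  cls <- pairing_class(g, t)
  M <- matrix(0, L, 4L, dimnames = list(NULL, c("match", "mm1", "mm2", "mm3")))
  M[cbind(seq_len(L), cls)] <- 1
  M
}

# class 1 = complementary; 2..4 = mismatch offsets 1..3
pairing_class <- function(g, t) {
  comp <- WC_COMP[g]
  1L + (match(t, DNA_BASES) - match(comp, DNA_BASES)) %% 4L
}

#' @rdname encode_pairing
#' @param matrix an encoded pairing matrix.
#' @export
decode_pairing <- function(matrix, guide) {
  g <- canon_base(seq_chars(guide))
  cls <- max.col(matrix)
  comp <- WC_COMP[g]
  idx <- (match(comp, DNA_BASES) + (cls - 1L) - 1L) %% 4L + 1L
  paste(DNA_BASES[idx], collapse = "")
}

seq_chars <- function(x) {
  if (length(x) == 1L && is.character(x)) strsplit(x, "")[[1]] else as.character(x)
}

#' Encode a gRNA-target alignment in the 13-channel in vivo representation
#'
#' Produces the 25-position x 13-channel binary matrix used by the in vivo
#' models: 4 channels one-hot encode the reference (PAM + guide) base, 4
#' channels one-hot encode a DNA substitution (set only where the aligned
#' target base differs from the reference), 4 channels one-hot encode a DNA
#' insertion, and 1 channel flags a DNA deletion. Column layout is fixed as
#' PAM-proximal first: 3 PAM columns, then the 20 guide columns, then up to
#' 2 columns absorbing DNA insertions. Unused (padding) columns are all
#' zero.
#'
#' The aligned target string is read against the reference \code{pam + guide}
#' (guide U converted to T): uppercase A/C/G/T consume one reference
#' position (substitution if different from the reference base), \code{"-"}
#' consumes one reference position and sets the deletion bit, and lowercase
#' a/c/g/t denote inserted target bases occupying their own column. At most
#' 2 insertions are accepted (the padding budget); longer alignments are
#' rejected rather than truncated.
#'
#' @param guide 20-nt guide sequence over A,C,G,U/T.
#' @param pam 3-nt PAM over A,C,G,T.
#' @param target_alignment aligned target string (defaults to the perfect
#'   match, i.e. the reference itself).
#' @return \code{25 x 13} binary matrix with an attribute \code{"n_columns"}
#'   giving the number of used alignment columns.
#' @export
encode_invivo <- function(guide, pam, target_alignment = NULL) {
  g <- canon_base(seq_chars(guide))
  p <- canon_base(seq_chars(pam))
  if (length(g) != 20L || any(!g %in% DNA_BASES))
    stop("guide must be a 20-nt sequence over A,C,G,U/T")
  if (length(p) != 3L || any(!p %in% DNA_BASES))
    stop("pam must be a 3-nt DNA sequence")
  ref <- c(p, g)
  if (is.null(target_alignment)) target_alignment <- paste(ref, collapse = "")
  al <- seq_chars(target_alignment)
  if (length(al) > 25L)
    stop("alignment has ", length(al), " columns; at most 25 are allowed ",
         "(3 PAM + 20 guide + 2 insertion-padding)")
  is_ins <- al %in% c("a", "c", "g", "t")
  is_del <- al == "-"
  is_sub <- al %in% DNA_BASES
  bad <- !(is_ins | is_del | is_sub)
  if (any(bad))
    stop("illegal alignment character(s): ",
         paste(unique(al[bad]), collapse = ", "))
  if (sum(is_ins) > 2L)
    stop("alignment has ", sum(is_ins), " insertions; at most 2 fit the ",
         "padding budget")
  if (sum(!is_ins) != 23L)
    stop("alignment must consume exactly 23 reference positions (PAM+guide); ",
         "got ", sum(!is_ins))
  M <- matrix(0, 25L, 13L,
              dimnames = list(NULL, c(paste0("ref_", DNA_BASES),
                                      paste0("sub_", DNA_BASES),
                                      paste0("ins_", DNA_BASES), "del")))
  ptr <- 0L
  for (col in seq_along(al)) {
    ch <- al[col]
    if (ch %in% c("a", "c", "g", "t")) {
      M[col, 8L + match(toupper(ch), DNA_BASES)] <- 1
    } else {
      ptr <- ptr + 1L
      b <- ref[ptr]
      M[col, match(b, DNA_BASES)] <- 1
      if (ch == "-") {
        M[col, 13L] <- 1
      } else if (ch != b) {
        M[col, 4L + match(ch, DNA_BASES)] <- 1
      }
    }
  }
  attr(M, "n_columns") <- length(al)
  M
}

#' Decode a 13-channel encoding back to its alignment
#'
#' Inverse of \code{\link{encode_invivo}} on canonical alignments.
#'
#' @param matrix a \code{25 x 13} encoded alignment.
#' @return list with \code{guide}, \code{pam}, \code{target_alignment}.
#' @export
decode_invivo <- function(matrix) {
  stopifnot(nrow(matrix) == 25L, ncol(matrix) == 13L)
  ref <- character(); al <- character()
  for (col in seq_len(25L)) {
    row <- matrix[col, ]
    if (all(row == 0)) next
    ins <- which(row[9:12] == 1)
    if (length(ins)) { al <- c(al, tolower(DNA_BASES[ins])); next }
    b <- DNA_BASES[which(row[1:4] == 1)]
    ref <- c(ref, b)
    if (row[13] == 1) al <- c(al, "-")
    else {
      sub <- which(row[5:8] == 1)
      al <- c(al, if (length(sub)) DNA_BASES[sub] else b)
    }
  }
  list(guide = paste(ref[4:23], collapse = ""),
       pam = paste(ref[1:3], collapse = ""),
       target_alignment = paste(al, collapse = ""))
}
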