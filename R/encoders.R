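# Sequence encoders: one-hot (binary), Kmer, ENAC, CKSNAP, NCP.
#
# All encoders use the fixed base order A, C, G, T(U) and treat T and U as
# the same base, so a sequence and its alphabet-normalized image encode
# identically. Feature values are plain doubles; no scaling is applied.

ENCODER_FAMILIES <- c("binary", "kmer", "enac", "cksnap", "ncp")

# NCP chemical-property triples (ring structure, hydrogen bonding,
# chemical functionality): A=(1,1,1), C=(0,1,0), G=(1,0,0), U/T=(0,0,1).
NCP_TABLE <- matrix(c(1, 1, 1,
                      0, 1, 0,
                      1, 0, 0,
                      0, 0, 1),
                    nrow = 4, byrow = TRUE,
                    dimnames = list(DNA_BASES, c("ring", "hbond", "func")))

# Map a sequence to base indices 1..4 under A,C,G,T(U); error on anything else.
seq_to_idx <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars[chars == "U"] <- "T"
  idx <- match(chars, DNA_BASES)
  if (anyNA(idx))
    stop("invalid character \"", chars[which(is.na(idx))[1]],
         "\" in sequence", call. = FALSE)
  idx
}

# All k-mers over A,C,G,T in lexicographic order.
kmer_levels <- function(k, bases = DNA_BASES) {
  sort(do.call(paste0, expand.grid(rep(list(bases), k),
                                   stringsAsFactors = FALSE)))
}

#' Define an encoding scheme
#'
#' A scheme is an encoder family plus its integer parameter: `k` for `kmer`
#' (any k >= 1), window width `w` for `enac` (w >= 1), and the maximum gap
#' for `cksnap` (>= 0; the vector concatenates all gaps 0..param). `binary`
#' and `ncp` take no parameter.
#'
#' @param family one of "binary", "kmer", "enac", "cksnap", "ncp".
#' @param param integer parameter, or NA for binary/ncp.
#' @return An `encoding_scheme` object.
#' @export
encoding_scheme <- function(family, param = NA_integer_) {
  family <- match.arg(family, ENCODER_FAMILIES)
  if (family %in% c("binary", "ncp")) {
    param <- NA_integer_
  } else {
    param <- as.integer(param)
    if (is.na(param))
      stop("scheme ", family, " requires an integer parameter", call. = FALSE)
    min_p <- if (family == "cksnap") 0L else 1L
    if (param < min_p)
      stop("scheme ", family, " parameter must be >= ", min_p, call. = FALSE)
  }
  structure(list(family = family, param = param), class = "encoding_scheme")
}

#' @export
print.encoding_scheme <- function(x, ...) {
  cat(scheme_label(x), "\n")
  invisible(x)
}

#' Human-readable scheme label, e.g. "kmer-3" or "binary"
#' @param scheme an `encoding_scheme`.
#' @return character label.
#' @export
scheme_label <- function(scheme) {
  if (is.na(scheme$param)) scheme$family
  else paste0(scheme$family, "-", scheme$param)
}

#' Feature-vector length of a scheme for sequence length L
#'
#' Closed forms: binary 4L; kmer(k) 4^k; enac(w) 4(L-w+1); cksnap(k)
#' 16(k+1); ncp 3L.
#'
#' @param scheme an `encoding_scheme`.
#' @param length common sequence length L.
#' @return integer feature count.
#' @export
scheme_dim <- function(scheme, length) {
  as.integer(switch(scheme$family,
                    binary = 4L * length,
                    kmer   = 4^scheme$param,
                    enac   = 4L * (length - scheme$param + 1L),
                    cksnap = 16L * (scheme$param + 1L),
                    ncp    = 3L * length))
}

#' The full fifteen-scheme grid
#'
#' Returns, in order: binary; kmer k=2..5; enac w=2..5; cksnap k=1..5; ncp.
#'
#' @return list of `encoding_scheme` objects of length 15.
#' @export
enumerate_schemes <- function() {
  c(list(encoding_scheme("binary")),
    lapply(2:5, function(k) encoding_scheme("kmer", k)),
    lapply(2:5, function(w) encoding_scheme("enac", w)),
    lapply(1:5, function(k) encoding_scheme("cksnap", k)),
    list(encoding_scheme("ncp")))
}

#' One-hot (binary) encoding
#'
#' Each position becomes a 4-entry indicator block in base order A,C,G,T(U);
#' blocks are concatenated 5' to 3', giving a length-4L vector.
#'
#' @param sequence canonical nucleotide string.
#' @return numeric vector of length 4L.
#' @export
encode_binary <- function(sequence) {
  idx <- seq_to_idx(sequence)
  out <- numeric(4L * length(idx))
  out[4L * (seq_along(idx) - 1L) + idx] <- 1
  out
}

#' Kmer composition encoding
#'
#' Counts the L-k+1 overlapping k-mers and divides each count by the total
#' number of windows, so entries sum to 1. Entries are ordered
#' lexicographically over A,C,G,T.
#'
#' @param sequence canonical nucleotide string of length L >= k.
#' @param k k-mer size (>= 1).
#' @return numeric vector of length 4^k.
#' @export
encode_kmer <- function(sequence, k) {
  idx <- seq_to_idx(sequence)
  L <- length(idx)
  if (L < k) stop("sequence-too-short error: L=", L, " < k=", k, call. = FALSE)
  n_win <- L - k + 1L
  # lexicographic rank of each window: base-4 digits, first char most significant
  code <- integer(n_win)
  for (j in seq_len(k)) code <- code * 4L + (idx[j:(j + n_win - 1L)] - 1L)
  counts <- tabulate(code + 1L, nbins = 4L^k)
  counts / n_win
}

#' Enhanced nucleic acid composition (ENAC) encoding
#'
#' Slides a width-w window by steps of 1 (no partial windows) and records the
#' within-window base frequencies (denominator w) as a 4-entry block per
#' window, base order A,C,G,T(U).
#'
#' @param sequence canonical nucleotide string of length L >= w.
#' @param w window width (>= 1).
#' @return numeric vector of length 4(L-w+1).
#' @export
encode_enac <- function(sequence, w) {
  idx <- seq_to_idx(sequence)
  L <- length(idx)
  if (L < w) stop("sequence-too-short error: L=", L, " < w=", w, call. = FALSE)
  n_win <- L - w + 1L
  # cumulative indicator counts per base -> windowed counts by differencing
  ind <- matrix(0L, nrow = L + 1L, ncol = 4L)
  for (b in 1:4) ind[-1L, b] <- cumsum(idx == b)
  counts <- ind[(w + 1L):(L + 1L), , drop = FALSE] -
    ind[1:n_win, , drop = FALSE]
  as.numeric(t(counts)) / w
}

#' Composition of k-spaced nucleic acid pairs (CKSNAP) encoding
#'
#' For each gap g = 0..kmax, tabulates ordered base pairs (s_i, s_{i+g+1})
#' over the 16 pairs AA, AC, AG, AT, CA, ..., TT and divides by the number of
#' g-spaced pairs, L-g-1. Gap blocks are concatenated.
#'
#' @param sequence canonical nucleotide string of length L >= kmax + 2.
#' @param kmax maximum gap (>= 0).
#' @return numeric vector of length 16(kmax+1).
#' @export
encode_cksnap <- function(sequence, kmax) {
  idx <- seq_to_idx(sequence)
  L <- length(idx)
  if (L < kmax + 2L)
    stop("sequence-too-short error: L=", L, " < kmax+2=", kmax + 2L,
         call. = FALSE)
  blocks <- lapply(0:kmax, function(g) {
    n_pairs <- L - g - 1L
    first <- idx[1:n_pairs]
    second <- idx[(g + 2L):L]
    tabulate((first - 1L) * 4L + second, nbins = 16L) / n_pairs
  })
  unlist(blocks, use.names = FALSE)
}

#' Nucleotide chemical property (NCP) encoding
#'
#' Each base becomes its 3-coordinate chemical-property triple — A=(1,1,1),
#' C=(0,1,0), G=(1,0,0), U=(0,0,1), with T receiving U's triple — and the
#' triples are concatenated 5' to 3'.
#'
#' @param sequence canonical nucleotide string.
#' @return numeric vector of length 3L.
#' @export
encode_ncp <- function(sequence) {
  idx <- seq_to_idx(sequence)
  as.numeric(t(NCP_TABLE[idx, , drop = FALSE]))
}

encode_one <- function(sequence, scheme) {
  switch(scheme$family,
         binary = encode_binary(sequence),
         kmer   = encode_kmer(sequence, scheme$param),
         enac   = encode_enac(sequence, scheme$param),
         cksnap = encode_cksnap(sequence, scheme$param),
         ncp    = encode_ncp(sequence))
}

scheme_feature_names <- function(scheme, length) {
  pos <- seq_len(length)
  switch(scheme$family,
         binary = paste0("pos", rep(pos, each = 4L), "_",
                         rep(DNA_BASES, length)),
         kmer   = kmer_levels(scheme$param),
         enac   = paste0("win", rep(seq_len(length - scheme$param + 1L),
                                    each = 4L), "_",
                         rep(DNA_BASES, length - scheme$param + 1L)),
         cksnap = paste0("gap", rep(0:scheme$param, each = 16L), "_",
                         rep(kmer_levels(2L), scheme$param + 1L)),
         ncp    = paste0("pos", rep(pos, each = 3L), "_",
                         rep(colnames(NCP_TABLE), length)))
}

#' Encode a sequence set as a feature matrix
#'
#' Row i of the result is the per-sequence encoding of record i. The returned
#' `feature_matrix` carries the scheme, ordered feature names, record ids,
#' and the 0/1 labels.
#'
#' @param records a `seq_records` data frame of equal-length sequences.
#' @param scheme an `encoding_scheme`.
#' @param length declared sequence length; required only when `records` is
#'   empty (to size the empty matrix), otherwise taken from the records.
#' @return A `feature_matrix` object.
#' @export
encode_dataset <- function(records, scheme, length = NULL) {
  stopifnot(inherits(records, "seq_records"),
            inherits(scheme, "encoding_scheme"))
  if (nrow(records) == 0L) {
    if (is.null(length))
      stop("declared length required to encode an empty record set",
           call. = FALSE)
    L <- as.integer(length)
  } else {
    lens <- nchar(records$sequence)
    if (base::length(unique(lens)) != 1L)
      stop("heterogeneous-length error: lengths ",
           paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
    L <- lens[1]
  }
  p <- scheme_dim(scheme, L)
  if (p <= 0L || (scheme$family == "kmer" && L < scheme$param) ||
      (scheme$family == "cksnap" && L < scheme$param + 2L))
    stop("sequence length ", L, " incompatible with scheme ",
         scheme_label(scheme), call. = FALSE)
  values <- matrix(0, nrow = nrow(records), ncol = p)
  for (i in seq_len(nrow(records))) {
    values[i, ] <- tryCatch(encode_one(records$sequence[i], scheme),
                            error = function(e)
                              stop("record ", records$id[i], ": ",
                                   conditionMessage(e), call. = FALSE))
  }
  fnames <- scheme_feature_names(scheme, L)
  dimnames(values) <- list(records$id, fnames)
  structure(list(values = values, scheme = scheme, feature_names = fnames,
                 record_ids = records$id, labels = records$label,
                 length = L),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d records x %d features (%s, L=%d)\n",
              nrow(x$values), ncol(x$values), scheme_label(x$scheme), x$length))
  invisible(x)
}

#' Export a feature matrix as CSV plus a JSON scheme sidecar
#'
#' The CSV has columns `id`, `label`, then one column per feature (header =
#' feature names). The sidecar `<path>.json` records the scheme family,
#' parameter, and sequence length so the matrix can be re-imported.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(id = fm$record_ids, label = fm$labels,
                   fm$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta <- list(family = fm$scheme$family, param = fm$scheme$param,
               length = fm$length)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' Import a feature matrix written by [write_feature_csv()]
#' @param path CSV path (expects the `<path>.json` sidecar next to it).
#' @return A `feature_matrix`.
#' @export
read_feature_csv <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  scheme <- encoding_scheme(meta$family,
                            if (is.null(meta$param)) NA_integer_ else meta$param)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(values) <- list(df$id, colnames(df)[-(1:2)])
  structure(list(values = values, scheme = scheme,
                 feature_names = colnames(values),
                 record_ids = as.character(df$id),
                 labels = as.integer(df$label),
                 length = as.integer(meta$length)),
            class = "feature_matrix")
}
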