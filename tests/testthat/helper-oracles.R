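# Independent brute-force oracles used to cross-check the encoders and the
# AUC estimator. These enumerate windows/pairs and count by direct string
# comparison; they share no code with the implementations they check.

BASES4 <- c("A", "C", "G", "T")

# all k-mers over A,C,G,T in lexicographic order (oracle-side copy)
oracle_levels <- lapply(1:3, function(k)
  sort(do.call(paste0, expand.grid(rep(list(BASES4), k),
                                   stringsAsFactors = FALSE))))

all_seqs_of_length <- function(n) {
  apply(do.call(expand.grid, rep(list(BASES4), n)), 1, paste0, collapse = "")
}

rand_seqs <- function(n, L, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste0(sample(BASES4, L, replace = TRUE), collapse = ""), "")
}

rand_records <- function(n, L, seed, label = NULL) {
  if (is.null(label)) {
    set.seed(seed + 1L)
    label <- rbinom(n, 1, 0.5)
    if (length(unique(label)) < 2) label[1:2] <- c(0L, 1L)
  }
  seq_records(id = sprintf("r%d", seq_len(n)),
              sequence = rand_seqs(n, L, seed), label = label)
}

# Eq-2 oracle: count each k-mer type over the overlapping windows.
oracle_kmer <- function(seq, k) {
  L <- nchar(seq)
  wins <- substring(seq, 1:(L - k + 1), k:L)
  vapply(oracle_levels[[k]], function(t) sum(wins == t), 0, USE.NAMES = FALSE) / length(wins)
}

# ENAC oracle: per sliding window, frequency of each base.
oracle_enac <- function(seq, w) {
  L <- nchar(seq)
  unlist(lapply(1:(L - w + 1), function(i) {
    ch <- strsplit(substr(seq, i, i + w - 1), "")[[1]]
    vapply(BASES4, function(b) sum(ch == b), 0, USE.NAMES = FALSE) / w
  }), use.names = FALSE)
}

# Eq-3 oracle: for each gap g, count each ordered pair (s_i, s_{i+g+1})
# over the L-g-1 g-spaced pairs.
oracle_cksnap <- function(seq, kmax) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  unlist(lapply(0:kmax, function(g) {
    pairs <- paste0(ch[1:(L - g - 1)], ch[(g + 2):L])
    vapply(oracle_levels[[2]], function(t) sum(pairs == t), 0, USE.NAMES = FALSE) / (L - g - 1)
  }), use.names = FALSE)
}

# one-hot oracle: indicator lookup per position
oracle_binary <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  unlist(lapply(ch, function(b) as.numeric(BASES4 == b)), use.names = FALSE)
}

# NCP oracle: the four printed chemical-property triples
oracle_ncp_table <- list(A = c(1, 1, 1), C = c(0, 1, 0),
                         G = c(1, 0, 0), T = c(0, 0, 1), U = c(0, 0, 1))
oracle_ncp <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  unlist(oracle_ncp_table[ch], use.names = FALSE)
}

# AUC oracle: all positive-negative pairs, ties at 1/2.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
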