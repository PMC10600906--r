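#' Construct a labeled sequence set
#'
#' A sequence set is the package's central container: a `data.frame` with one
#' row per fixed-length nucleotide window, columns `id`, `sequence`, `label`
#' (1 = 6mA-positive, 0 = negative), `species`, and `alphabet` ("DNA" or
#' "RNA"). Sequences are uppercased; only the four canonical bases of the
#' inferred alphabet are accepted. IUPAC ambiguity codes (N, R, Y, ...) are
#' rejected rather than masked, since silent masking would corrupt the
#' frequency-based encodings downstream.
#'
#' @param id character vector of record identifiers.
#' @param sequence character vector of nucleotide strings (case-insensitive).
#' @param label integer vector of 0/1 class labels (recycled if length 1).
#' @param species free-text species tag (recycled).
#' @param alphabet "DNA", "RNA", or NULL to infer per record (U implies RNA,
#'   T implies DNA; a sequence with neither defaults to DNA).
#' @return A `data.frame` of class `seq_records`.
#' @export
seq_records <- function(id, sequence, label, species = "unknown", alphabet = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != length(id))
    stop("id and sequence must have equal length", call. = FALSE)
  label <- as.integer(rep_len(label, length(id)))
  if (length(id) && !all(label %in% c(0L, 1L)))
    stop("labels must be 0 or 1", call. = FALSE)
  species <- rep_len(as.character(species), length(id))

  if (length(id) && any(!nzchar(sequence)))
    stop("empty sequence for record ", id[!nzchar(sequence)][1], call. = FALSE)

  has_t <- grepl("T", sequence, fixed = TRUE)
  has_u <- grepl("U", sequence, fixed = TRUE)
  mixed <- has_t & has_u
  if (any(mixed))
    stop("alphabet error: record ", id[mixed][1],
         " mixes T and U in one sequence", call. = FALSE)
  if (is.null(alphabet)) {
    alphabet <- ifelse(has_u, "RNA", "DNA")
  } else {
    alphabet <- match.arg(alphabet, c("DNA", "RNA"))
    if (alphabet == "DNA" && any(has_u))
      stop("alphabet error: record ", id[has_u][1],
           " contains U but alphabet is DNA", call. = FALSE)
    if (alphabet == "RNA" && any(has_t))
      stop("alphabet error: record ", id[has_t][1],
           " contains T but alphabet is RNA", call. = FALSE)
    alphabet <- rep_len(alphabet, length(id))
  }

  bad <- regmatches(sequence, regexpr("[^ACGTU]", sequence))
  idx <- which(grepl("[^ACGTU]", sequence))
  if (length(idx))
    stop("invalid character \"", bad[1], "\" in record ", id[idx[1]],
         call. = FALSE)

  out <- data.frame(id = id, sequence = sequence, label = label,
                    species = species,
                    alphabet = if (length(id)) alphabet else character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read labeled sequences from a FASTA file
#'
#' One FASTA file holds one class (labels are not stored in FASTA; callers
#' pair a positive and a negative file). Wrapped sequences are accepted;
#' everything after ">" up to end of line is the id.
#'
#' @param path FASTA file path.
#' @param label 0/1 class label applied to every record in the file.
#' @param species species tag applied to every record.
#' @return A `seq_records` data frame.
#' @export
read_fasta <- function(path, label, species = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("empty-input error: no FASTA records in ", path, call. = FALSE)
  seq_records(id = names(set), sequence = as.character(set),
              label = label, species = species)
}

#' Write a sequence set to FASTA
#'
#' Writes standard unwrapped FASTA: a `>id` header line followed by the full
#' sequence on one line, so `read_fasta(write_fasta(x))` recovers ids and
#' sequences exactly. Labels are not written (one file per class).
#'
#' @param records a `seq_records` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(inherits(records, "seq_records"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  if (nrow(records))
    writeLines(paste0(">", records$id, "\n", records$sequence, collapse = "\n"),
               con)
  invisible(path)
}

#' Convert sequences between the DNA and RNA alphabets
#'
#' Substitutes T for U (target "DNA") or U for T (target "RNA"), leaving all
#' other characters and their order unchanged. Idempotent, and an involution
#' across targets. Needed because benchmark tables mix DNA-alphabet and
#' RNA-alphabet species.
#'
#' @param records a `seq_records` data frame.
#' @param target "DNA" or "RNA".
#' @return The converted `seq_records`.
#' @export
normalize_alphabet <- function(records, target = c("DNA", "RNA")) {
  stopifnot(inherits(records, "seq_records"))
  target <- match.arg(target)
  if (target == "DNA") {
    records$sequence <- gsub("U", "T", records$sequence, fixed = TRUE)
  } else {
    records$sequence <- gsub("T", "U", records$sequence, fixed = TRUE)
  }
  if (nrow(records)) records$alphabet <- target
  records
}

#' Validate a benchmark sequence set and summarize it
#'
#' Checks that all records share one length (optionally a given length) and,
#' when `require_center_A` is on, that the center position — 1-based index
#' (L+1)/2, defined only for odd L — is adenine in every record, as the
#' benchmark construction demands for both methylated and non-methylated
#' windows.
#'
#' @param records a non-empty `seq_records` data frame.
#' @param expected_length required common length, or NULL to accept any.
#' @param require_center_A check the center-adenine constraint (default TRUE).
#' @return A `dataset_summary` list: `n_positive`, `n_negative`, `length`,
#'   `species`, `alphabet`.
#' @export
validate_benchmark <- function(records, expected_length = NULL,
                               require_center_A = TRUE) {
  stopifnot(inherits(records, "seq_records"))
  if (!nrow(records)) stop("empty record set", call. = FALSE)
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1L)
    stop("heterogeneous-length error: lengths ",
         paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
  L <- lens[1]
  if (!is.null(expected_length) && L != expected_length)
    stop("length ", L, " does not match expected ", expected_length,
         call. = FALSE)
  if (require_center_A) {
    if (L %% 2L == 0L)
      stop("center-undefined error: even length ", L, call. = FALSE)
    center <- (L + 1L) %/% 2L
    base <- substr(records$sequence, center, center)
    bad <- records$id[base != "A"]
    if (length(bad))
      stop("center-violation error: non-A center in record(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out <- list(n_positive = sum(records$label == 1L),
              n_negative = sum(records$label == 0L),
              length = L,
              species = paste(unique(records$species), collapse = ","),
              alphabet = paste(unique(records$alphabet), collapse = ","))
  class(out) <- "dataset_summary"
  out
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("dataset: %d positive / %d negative, length %d nt, %s (%s)\n",
              x$n_positive, x$n_negative, x$length, x$species, x$alphabet))
  invisible(x)
}

#' Serialize a dataset summary as JSON
#' @param summary a `dataset_summary`.
#' @param path optional output path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
summary_to_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "dataset_summary"))
  js <- jsonlite::toJSON(unclass(summary), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Balance classes by seeded subsampling of the majority class
#'
#' Keeps every minority-class record and a uniform random subsample of the
#' majority class of equal size, mirroring how benchmark negatives are drawn
#' to match the number of positives. Deterministic for a fixed seed; relative
#' record order is preserved.
#'
#' @param records a `seq_records` data frame containing both classes.
#' @param seed integer RNG seed.
#' @return A balanced `seq_records` data frame.
#' @export
balance_classes <- function(records, seed = 1L) {
  stopifnot(inherits(records, "seq_records"))
  n1 <- sum(records$label == 1L)
  n0 <- sum(records$label == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("missing-class error: both classes must be present", call. = FALSE)
  if (n1 == n0) return(records)
  maj <- if (n1 > n0) 1L else 0L
  n_keep <- min(n1, n0)
  maj_idx <- which(records$label == maj)
  keep <- with_local_seed(seed, sort(sample(maj_idx, n_keep)))
  out <- records[sort(c(which(records$label != maj), keep)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("seq_records", "data.frame")
  out
}
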