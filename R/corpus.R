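#' Multi-type EHR corpus
#'
#' Container for the discrete observations the topic model consumes: per
#' patient, counts of categorical features over `T` data types (each type `t`
#' has its own vocabulary of size `W[t]`), plus categorical lab records.
#' A lab record for patient `j`, lab `l` gives the frequency with which
#' result state `v` (of `V[l]` states) was seen.  Whether a lab was taken at
#' all is the observation indicator `r[l, j]`: it is 1 exactly when at least
#' one lab record exists for `(l, j)`, and the model treats the remaining
#' `(l, j)` pairs as missing results whose missingness is informative.
#'
#' @param counts data.frame with integer columns `patient`, `type`,
#'   `feature`, `count` (1-based indices, counts >= 1). May have zero rows.
#' @param labs data.frame with integer columns `patient`, `lab`, `state`,
#'   `freq` (1-based, freq >= 1). May have zero rows.
#' @param n_patients integer, the number of patients `D` (>= 0).
#' @param n_features integer vector, vocabulary size per data type (`W`).
#'   Its length defines the number of types `T`.
#' @param n_states integer vector, number of result states per lab (`V`).
#'   Its length defines the number of labs `L`. May be length zero.
#' @param r optional `L x D` 0/1 matrix of observation indicators. By
#'   default derived from `labs` (1 iff a record exists); supplying it is
#'   only useful to construct deliberately inconsistent corpora for
#'   [validate_corpus()].
#'
#' @return An object of class `mixehr_corpus` with fields `D`, `W`, `V`,
#'   `counts`, `labs`, `r`.
#' @seealso [validate_corpus()], [read_corpus()], [write_corpus()],
#'   [sample_corpus()]
#' @export
mixehr_corpus <- function(counts, labs, n_patients, n_features,
                          n_states = integer(0), r = NULL) {
  D <- as.integer(n_patients)
  W <- as.integer(n_features)
  V <- as.integer(n_states)
  L <- length(V)
  counts <- as.data.frame(counts)
  labs <- as.data.frame(labs)
  if (nrow(counts) == 0L)
    counts <- data.frame(patient = integer(0), type = integer(0),
                         feature = integer(0), count = integer(0))
  if (nrow(labs) == 0L)
    labs <- data.frame(patient = integer(0), lab = integer(0),
                       state = integer(0), freq = integer(0))
  stopifnot(all(c("patient", "type", "feature", "count") %in% names(counts)),
            all(c("patient", "lab", "state", "freq") %in% names(labs)))
  counts <- counts[, c("patient", "type", "feature", "count")]
  labs <- labs[, c("patient", "lab", "state", "freq")]
  counts[] <- lapply(counts, as.integer)
  labs[] <- lapply(labs, as.integer)
  ord <- order(counts$patient, counts$type, counts$feature)
  counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- NULL
  ord <- order(labs$patient, labs$lab, labs$state)
  labs <- labs[ord, , drop = FALSE]
  rownames(labs) <- NULL
  if (is.null(r)) {
    r <- matrix(0L, nrow = L, ncol = D)
    if (nrow(labs) > 0L && L > 0L && D > 0L)
      r[cbind(labs$lab, labs$patient)] <- 1L
  } else {
    r <- matrix(as.integer(r), nrow = L, ncol = D)
  }
  structure(list(D = D, W = W, V = V, counts = counts, labs = labs, r = r),
            class = "mixehr_corpus")
}

#' @export
print.mixehr_corpus <- function(x, ...) {
  cat("<mixehr_corpus> ", x$D, " patients, ", length(x$W),
      " data type(s) [W = ", paste(x$W, collapse = ","), "], ",
      length(x$V), " lab(s)\n", sep = "")
  cat("  ", nrow(x$counts), " count records (", sum(x$counts$count),
      " tokens), ", nrow(x$labs), " lab records, ",
      if (length(x$V)) sum(x$r) else 0L, " observed lab-patient pairs\n",
      sep = "")
  invisible(x)
}

#' Number of tokens per patient and type
#'
#' Returns the `D x T` matrix of per-patient token totals `M[j, t]`.
#' @param corpus a [mixehr_corpus()].
#' @return integer matrix `D x T`.
#' @export
token_totals <- function(corpus) {
  T_ <- length(corpus$W)
  M <- matrix(0L, nrow = corpus$D, ncol = T_)
  if (nrow(corpus$counts) > 0L) {
    agg <- stats::aggregate(count ~ patient + type, data = corpus$counts, FUN = sum)
    M[cbind(agg$patient, agg$type)] <- as.integer(agg$count)
  }
  M
}

#' Validate a corpus against its structural invariants
#'
#' Checks index ranges, positivity of counts and frequencies, duplicate
#' records, and the coupling between lab records and the observation
#' indicator (`r[l, j] = 0` implies no record for `(l, j)`; `r[l, j] = 1`
#' implies at least one).  Violations are returned, never raised.
#'
#' @param corpus a [mixehr_corpus()].
#' @return character vector of human-readable violations; empty if the
#'   corpus is valid.
#' @export
validate_corpus <- function(corpus) {
  v <- character(0)
  cn <- corpus$counts
  lb <- corpus$labs
  D <- corpus$D; W <- corpus$W; V <- corpus$V; L <- length(V)
  bad <- function(rows, what) {
    if (length(rows)) sprintf("%s: record %s", what, paste(rows, collapse = ","))
    else character(0)
  }
  if (nrow(cn)) {
    v <- c(v, bad(which(cn$patient < 1L | cn$patient > D), "count patient out of range"))
    v <- c(v, bad(which(cn$type < 1L | cn$type > length(W)), "count type out of range"))
    okt <- cn$type >= 1L & cn$type <= length(W)
    oor <- which(okt & (cn$feature < 1L | cn$feature > W[pmin(pmax(cn$type, 1L), length(W))]))
    if (length(oor))
      v <- c(v, sprintf("feature index out of declared range (feature %d, type %d): record %d",
                        cn$feature[oor], cn$type[oor], oor))
    v <- c(v, bad(which(cn$count < 1L), "non-positive count"))
    key <- paste(cn$patient, cn$type, cn$feature)
    v <- c(v, bad(which(duplicated(key)), "duplicate (patient,type,feature) record"))
  }
  if (nrow(lb)) {
    v <- c(v, bad(which(lb$patient < 1L | lb$patient > D), "lab patient out of range"))
    v <- c(v, bad(which(lb$lab < 1L | lb$lab > L), "lab id out of range"))
    okl <- lb$lab >= 1L & lb$lab <= L
    oor <- which(okl & (lb$state < 1L | lb$state > V[pmin(pmax(lb$lab, 1L), max(L, 1L))]))
    v <- c(v, bad(oor, "lab state out of declared range"))
    v <- c(v, bad(which(lb$freq < 1L), "non-positive frequency"))
    key <- paste(lb$patient, lb$lab, lb$state)
    v <- c(v, bad(which(duplicated(key)), "duplicate (patient,lab,state) record"))
  }
  if (L > 0L && D > 0L) {
    has_rec <- matrix(FALSE, nrow = L, ncol = D)
    if (nrow(lb)) {
      ok <- lb$lab >= 1L & lb$lab <= L & lb$patient >= 1L & lb$patient <= D
      has_rec[cbind(lb$lab[ok], lb$patient[ok])] <- TRUE
    }
    mism0 <- which(corpus$r == 0L & has_rec, arr.ind = TRUE)
    if (nrow(mism0))
      v <- c(v, sprintf("record for unobserved lab (lab %d, patient %d)",
                        mism0[, 1], mism0[, 2]))
    mism1 <- which(corpus$r == 1L & !has_rec, arr.ind = TRUE)
    if (nrow(mism1))
      v <- c(v, sprintf("observed lab without record (lab %d, patient %d)",
                        mism1[, 1], mism1[, 2]))
  }
  v
}

#' Read a corpus from its three tab-separated files
#'
#' The on-disk format is three TSVs: a meta file declaring the dimensions
#' (`field`, `id`, `value` columns with rows `n_patients`, one `type` row
#' per data type giving its vocabulary size, one `lab` row per lab giving
#' its number of result states), a counts file (`patient`, `type`,
#' `feature`, `count`) and a labs file (`patient`, `lab`, `state`, `freq`).
#' All indices are 1-based on disk. Missingness is implicit: a lab is
#' observed for a patient iff a row for the pair exists in the labs file.
#'
#' @param counts_path,labs_path,meta_path file paths.
#' @return a validated [mixehr_corpus()].
#' @export
read_corpus <- function(counts_path, labs_path, meta_path) {
  for (p in c(counts_path, labs_path, meta_path))
    if (!file.exists(p)) stop("file not found: ", p)
  meta <- .read_meta(meta_path)
  drow <- meta$field == "n_patients"
  if (sum(drow) != 1L) stop("meta file must declare n_patients exactly once")
  D <- as.integer(meta$value[drow])
  trows <- meta[meta$field == "type", , drop = FALSE]
  lrows <- meta[meta$field == "lab", , drop = FALSE]
  W <- integer(nrow(trows)); W[as.integer(trows$id)] <- as.integer(trows$value)
  V <- integer(nrow(lrows))
  if (nrow(lrows)) V[as.integer(lrows$id)] <- as.integer(lrows$value)
  counts <- .read_tsv(counts_path, c("patient", "type", "feature", "count"))
  labs <- .read_tsv(labs_path, c("patient", "lab", "state", "freq"))
  corpus <- mixehr_corpus(counts, labs, D, W, V)
  viol <- validate_corpus(corpus)
  if (length(viol))
    stop("invalid corpus:\n  ", paste(utils::head(viol, 10L), collapse = "\n  "))
  corpus
}

.read_meta <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) < 1L) stop("parse error in ", path, ": empty meta file")
  header <- strsplit(raw[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("field", "id", "value")))
    stop("parse error in ", path, " line 1: expected header 'field\tid\tvalue'")
  if (length(raw) == 1L)
    return(data.frame(field = character(0), id = integer(0), value = integer(0)))
  parts <- strsplit(raw[-1L], "\t", fixed = TRUE)
  fld <- vapply(parts, `[`, "", 1L)
  id <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", "")))
  val <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", "")))
  if (any(is.na(val)))
    stop(sprintf("parse error in %s line %d: non-integer value",
                 path, which(is.na(val))[1L] + 1L))
  data.frame(field = fld, id = id, value = val, stringsAsFactors = FALSE)
}

.read_tsv <- function(path, cols) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(integer(0)), length(cols)), cols))
    return(out)
  }
  header <- strsplit(raw[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, cols))
    stop(sprintf("parse error in %s line 1: expected header '%s', got '%s'",
                 path, paste(cols, collapse = "\t"), raw[1L]))
  body <- raw[-1L]
  if (length(body) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(integer(0)), length(cols)), cols))
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(cols)))
    stop(sprintf("parse error in %s line %d: expected %d fields, got %d",
                 path, which(nf != length(cols))[1L] + 1L, length(cols),
                 nf[nf != length(cols)][1L]))
  m <- matrix(unlist(parts), ncol = length(cols), byrow = TRUE)
  vals <- suppressWarnings(matrix(as.integer(m), ncol = length(cols)))
  badline <- which(rowSums(matrix(is.na(vals), ncol = length(cols))) > 0L)
  if (length(badline))
    stop(sprintf("parse error in %s line %d: non-integer field",
                 path, badline[1L] + 1L))
  out <- as.data.frame(vals)
  names(out) <- cols
  out
}

#' Write a corpus to its three tab-separated files
#'
#' Inverse of [read_corpus()]; `read_corpus(write_corpus(x))` is the
#' identity on valid corpora.
#'
#' @param corpus a [mixehr_corpus()].
#' @param dir directory to write `meta.tsv`, `counts.tsv`, `labs.tsv` into
#'   (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(field = "n_patients", id = NA_integer_, value = corpus$D)
  if (length(corpus$W))
    meta <- rbind(meta, data.frame(field = "type", id = seq_along(corpus$W),
                                   value = corpus$W))
  if (length(corpus$V))
    meta <- rbind(meta, data.frame(field = "lab", id = seq_along(corpus$V),
                                   value = corpus$V))
  paths <- file.path(dir, c("meta.tsv", "counts.tsv", "labs.tsv"))
  utils::write.table(meta, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(corpus$counts, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(corpus$labs, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Extract one patient's observations
#'
#' Convenience accessor returning the light per-patient record structure
#' used by [infer_patient_mixture()] and the imputation/prediction helpers.
#'
#' @param corpus a [mixehr_corpus()].
#' @param j patient index.
#' @return list with data.frames `tokens` (`type`, `feature`, `count`) and
#'   `labs` (`lab`, `state`, `freq`).
#' @export
patient_record <- function(corpus, j) {
  stopifnot(j >= 1L, j <= corpus$D)
  ctok <- corpus$counts[corpus$counts$patient == j, c("type", "feature", "count")]
  clab <- corpus$labs[corpus$labs$patient == j, c("lab", "state", "freq")]
  rownames(ctok) <- rownames(clab) <- NULL
  list(tokens = ctok, labs = clab)
}
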