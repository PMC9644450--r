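#' Read bags from a long-form delimited table
#'
#' The on-disk format is one row per instance with columns
#' `bag_id`, `label`, optionally `instance_id`, then the feature columns
#' `f1 ... fp`. Row order defines instance order within each bag (which
#' matters for truncation) and the order of first appearance defines bag
#' order. An optional `primary` column (0/1) restores ground-truth flags
#' written by [write_bags()] for synthetic data.
#'
#' @param path File path.
#' @param sep Field separator; tab by default, comma accepted.
#' @return List of [bag()] objects (empty list, with a warning, for a file
#'   with a header and no rows).
#' @export
read_bags <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("bag_id", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (length(fcols) == 0L) {
    stop("format error: no feature columns f1..fp found", call. = FALSE)
  }
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  if (nrow(df) == 0L) {
    warning("empty bag file: ", path)
    return(list())
  }
  bad <- which(!(df$label %in% c(0, 1)))
  if (length(bad) > 0L) {
    stop("format error: non-binary label at data row ", bad[1],
         " (value ", df$label[bad[1]], ")", call. = FALSE)
  }
  feat <- as.matrix(df[, fcols, drop = FALSE])
  if (!is.numeric(feat) || anyNA(feat)) {
    stop("format error: non-numeric or missing feature values", call. = FALSE)
  }
  ids <- unique(df$bag_id)
  lapply(ids, function(id) {
    rows <- which(df$bag_id == id)
    lab <- unique(df$label[rows])
    if (length(lab) != 1L) {
      stop("format error: bag ", id, " has inconsistent labels",
           call. = FALSE)
    }
    bag(instances = feat[rows, , drop = FALSE],
        label = lab,
        bag_id = id,
        instance_ids = if ("instance_id" %in% names(df))
          as.character(df$instance_id[rows]) else NULL,
        primary_flags = if ("primary" %in% names(df))
          df$primary[rows] != 0 else NULL)
  })
}

#' Write bags to a long-form delimited table
#'
#' Inverse of [read_bags()]: feature values are serialized with 17
#' significant digits so a write/read round trip reproduces the doubles
#' bit-exactly, and row order preserves bag and within-bag instance order.
#' Ground-truth `primary_flags`, when present on every bag, are emitted as a
#' 0/1 `primary` column.
#'
#' @param bags List of [bag()] objects.
#' @param path Output file path.
#' @param sep Field separator (tab default).
#' @return `path`, invisibly.
#' @export
write_bags <- function(bags, path, sep = "\t") {
  check_bag_list(bags)
  p <- ncol(bags[[1]]$instances)
  has_iid <- all(vapply(bags, function(b) !is.null(b$instance_ids),
                        logical(1)))
  has_primary <- all(vapply(bags, function(b) !is.null(b$primary_flags),
                            logical(1)))
  rows <- lapply(bags, function(b) {
    m <- bag_size(b)
    parts <- list(
      data.frame(bag_id = rep(b$bag_id, m), label = rep(b$label, m),
                 stringsAsFactors = FALSE),
      if (has_iid) data.frame(instance_id = b$instance_ids,
                              stringsAsFactors = FALSE),
      if (has_primary) data.frame(primary = as.integer(b$primary_flags)),
      as.data.frame(matrix(sprintf("%.17g", t(b$instances)),
                           nrow = m, byrow = TRUE,
                           dimnames = list(NULL, paste0("f", seq_len(p)))),
                    stringsAsFactors = FALSE))
    do.call(cbind, Filter(Negate(is.null), parts))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

atchley_env <- new.env(parent = emptyenv())

# md5 of the packaged resource; guards against silent corruption or edits.
ATCHLEY_MD5 <- "d52f8cb51162ca4a9968154d46fd4508"

#' The packaged Atchley factor table
#'
#' Five standardized numerical descriptors of amino-acid physicochemical
#' properties (polarity/hydrophobicity, secondary structure propensity,
#' size, codon composition, charge) for the 20 standard residues, as
#' published in the factor-analysis literature and widely used to embed
#' TCR CDR3 sequences. Loaded from a checksummed package resource.
#'
#' Per-factor means over the 20 residues are 0; the published scores have
#' unit spread for factors 1, 2 and 4, while factors 3 and 5 were released
#' on a wider scale (sd about 2.2 and 1.6).
#'
#' @return 20 x 5 numeric matrix, rownames = one-letter residue codes.
#' @export
atchley_table <- function() {
  if (is.null(atchley_env$table)) {
    path <- system.file("extdata", "atchley_factors.tsv",
                        package = "sparsemil", mustWork = TRUE)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, ATCHLEY_MD5)) {
      stop("Atchley factor resource failed its checksum: ", md5,
           call. = FALSE)
    }
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df$residue
    atchley_env$table <- m
  }
  atchley_env$table
}

#' Encode an amino-acid sequence as an Atchley factor matrix
#'
#' Maps each residue of a CDR3 (or any) amino-acid string to its five
#' Atchley factors, producing the `L x 5` matrix consumed by downstream
#' sequence encoders.
#'
#' @param sequence Character scalar over the 20 standard one-letter codes.
#' @return `nchar(sequence) x 5` numeric matrix, one row per residue.
#' @export
encode_atchley <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  tab <- atchley_table()
  residues <- strsplit(sequence, "")[[1]]
  if (length(residues) == 0L) {
    stop("invalid residue: empty sequence", call. = FALSE)
  }
  unknown <- which(!(residues %in% rownames(tab)))
  if (length(unknown) > 0L) {
    stop("invalid residue '", residues[unknown[1]], "' at position ",
         unknown[1], call. = FALSE)
  }
  out <- tab[residues, , drop = FALSE]
  dimnames(out) <- NULL
  out
}
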