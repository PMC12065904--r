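## Cross-link report normalization, deduplication and multi-engine consensus.
##
## Search-engine exports are first converted to a normalized long table (one
## row per cross-linked-peptide-to-spectrum match aggregated to a residue
## pair), then collapsed to unique inter-protein residue pairs carrying their
## provenance (engines, linkers, replicates), on which the consensus filter
## ("identified by at least two search engines") operates. Pair identity
## ignores provenance: the same residue pair seen with DSSO and DSBU is one
## unique inter-XL.

XL_COLUMNS <- c("protein_a", "residue_a", "protein_b", "residue_b",
                "linker", "engine", "replicate")

sniff_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Parse cross-link reports into normalized records
#'
#' Reads one or more delimited files (comma or tab, sniffed per file) and maps
#' their columns onto the normalized schema `protein_a`, `residue_a`,
#' `protein_b`, `residue_b`, `linker`, `engine`, `replicate` (plus optional
#' `score`). The link class (`inter`/`intra`) is derived from protein
#' identity, never read from the file.
#'
#' @param paths Character vector of file paths.
#' @param schema Optional named character vector mapping normalized column
#'   names to the file's column names (e.g. `c(protein_a = "Protein1")`).
#'   Unmapped normalized columns are looked up under their own names.
#' @return data.frame of cross-link records with a derived `link_class`
#'   column.
#' @export
parse_reports <- function(paths, schema = NULL) {
  recs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    raw <- read.csv(p, sep = sniff_delim(p), stringsAsFactors = FALSE,
                    check.names = FALSE)
    cols <- setNames(XL_COLUMNS, XL_COLUMNS)
    if (!is.null(schema)) cols[names(schema)] <- schema
    missing <- cols[!(cols %in% names(raw))]
    if (length(missing) > 0)
      stop("file '", p, "' lacks required column(s): ",
           paste(missing, collapse = ", "))
    out <- as.data.frame(lapply(cols, function(cc) raw[[cc]]),
                         stringsAsFactors = FALSE)
    for (rc in c("residue_a", "residue_b")) {
      v <- suppressWarnings(as.integer(out[[rc]]))
      bad <- which(is.na(v) | v < 1)
      if (length(bad) > 0)
        stop("file '", p, "', row ", bad[1], ": column ", rc,
             " is not a positive integer ('", out[[rc]][bad[1]], "')")
      out[[rc]] <- v
    }
    if ("score" %in% names(raw)) out$score <- raw$score
    out
  })
  recs <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  recs$link_class <- ifelse(recs$protein_a == recs$protein_b, "intra", "inter")
  recs
}

#' Shift construct-local residue numbering by per-protein offsets
#'
#' Search results are reported in construct-local coordinates; a per-protein
#' offset table converts them to reference (e.g. UniProt) numbering.
#'
#' @param records Cross-link records (as from [parse_reports()]).
#' @param offsets Named integer vector, offset added to residue numbers of
#'   each named protein.
#' @return The records with shifted residue numbers.
#' @export
apply_residue_offsets <- function(records, offsets) {
  for (p in names(offsets)) {
    records$residue_a[records$protein_a == p] <-
      records$residue_a[records$protein_a == p] + offsets[[p]]
    records$residue_b[records$protein_b == p] <-
      records$residue_b[records$protein_b == p] + offsets[[p]]
  }
  records
}

join_set <- function(x) paste(sort(unique(x)), collapse = ";")
split_set <- function(x) strsplit(x, ";", fixed = TRUE)

#' Collapse records to unique inter-protein cross-links
#'
#' Inter-class records are grouped by their unordered residue pair; provenance
#' (engines, linkers, replicates) is the union over the group, stored as
#' semicolon-joined sorted sets. Intra and loop links are excluded. The
#' operation is idempotent.
#'
#' @param records Cross-link records with `link_class`.
#' @return data.frame of unique inter-XLs: `protein_1`, `residue_1`,
#'   `protein_2`, `residue_2`, `engines`, `linkers`, `replicates`, `n_records`.
#' @export
unique_inter_xls <- function(records) {
  empty <- data.frame(protein_1 = character(), residue_1 = integer(),
                      protein_2 = character(), residue_2 = integer(),
                      engines = character(), linkers = character(),
                      replicates = character(), n_records = integer(),
                      stringsAsFactors = FALSE)
  inter <- records[records$link_class == "inter", , drop = FALSE]
  if (nrow(inter) == 0) return(empty)
  a <- paste0(inter$protein_a, "\r", inter$residue_a)
  b <- paste0(inter$protein_b, "\r", inter$residue_b)
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  key <- paste(lo, hi, sep = "\n")
  groups <- split(seq_len(nrow(inter)), key)
  rows <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    ends <- strsplit(unlist(strsplit(k, "\n", fixed = TRUE)), "\r",
                     fixed = TRUE)
    data.frame(protein_1 = ends[[1]][1],
               residue_1 = as.integer(ends[[1]][2]),
               protein_2 = ends[[2]][1],
               residue_2 = as.integer(ends[[2]][2]),
               engines = join_set(inter$engine[idx]),
               linkers = join_set(inter$linker[idx]),
               replicates = join_set(inter$replicate[idx]),
               n_records = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$protein_1, out$residue_1, out$protein_2, out$residue_2), ,
      drop = FALSE]
}

#' Multi-engine consensus filter
#'
#' Keeps unique inter-XLs identified by at least `min_engines` distinct search
#' engines. Idempotent; output is a subset of the input.
#'
#' @param xls Unique inter-XL table (from [unique_inter_xls()]).
#' @param min_engines Minimum number of distinct engines (default 2).
#' @return The filtered table.
#' @export
consensus_filter <- function(xls, min_engines = 2) {
  if (min_engines < 1) stop("min_engines must be >= 1")
  if (nrow(xls) == 0) return(xls)
  n_eng <- lengths(split_set(xls$engines))
  xls[n_eng >= min_engines, , drop = FALSE]
}

#' Provenance Venn category counts
#'
#' Partitions unique inter-XLs by their exact provenance membership set along
#' one dimension (engines or linkers). Categories are disjoint and exhaustive,
#' so counts sum to the number of XLs.
#'
#' @param xls Unique inter-XL table.
#' @param by `"engines"` or `"linkers"`.
#' @return Named integer vector; names are sorted memberships joined with
#'   `"+"` (e.g. `"DSBU+DSSO"`).
#' @export
venn_counts <- function(xls, by = c("engines", "linkers")) {
  by <- match.arg(by)
  if (nrow(xls) == 0) return(setNames(integer(), character()))
  cat <- vapply(split_set(xls[[by]]),
                function(x) paste(sort(x), collapse = "+"), character(1))
  tab <- table(cat)
  setNames(as.integer(tab), names(tab))
}
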