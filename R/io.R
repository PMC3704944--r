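#' @title Readers and writers for the pipeline's tabular formats
#' @description All tables are tab-separated with a header line; lines
#'   starting with `#` and blank lines are ignored. Malformed lines raise
#'   errors that name the offending line.
#' @name io_formats
NULL

# Parse a TSV file into a character matrix with the declared columns.
# Returns a zero-row matrix for an empty (or comments-only) file.
read_tsv_table <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- matrix(character(0), 0, length(columns),
                  dimnames = list(NULL, columns))
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < length(columns) ||
      !identical(header[seq_along(columns)], columns))
    stop(sprintf("%s: expected header '%s', found '%s'",
                 path, paste(columns, collapse = "\t"),
                 paste(header, collapse = "\t")))
  fields <- fields[-1L]
  lineno <- lineno[-1L]
  if (length(fields) == 0L) return(empty)
  nf <- lengths(fields)
  bad <- which(nf < length(columns))
  if (length(bad))
    stop(sprintf("%s: line %d has %d field(s), expected %d",
                 path, lineno[bad[1L]], nf[bad[1L]], length(columns)))
  out <- t(vapply(fields, function(f) f[seq_along(columns)],
                  character(length(columns))))
  colnames(out) <- columns
  rownames(out) <- as.character(lineno)
  out
}

#' Read binary molecular fingerprints
#'
#' In `"bit-table"` format the file has columns `drug_id` and
#' `fingerprint`, the latter a string of 0/1 characters of identical
#' length on every row. In `"smiles"` format the second column is named
#' `smiles` and fingerprints are computed with the ChemmineR atom-pair
#' descriptor backend (1024-bit by default).
#'
#' @param path TSV file.
#' @param format `"bit-table"` (default) or `"smiles"`.
#' @param fp_bits fingerprint length for the SMILES backend.
#' @return integer 0/1 matrix, one row per drug, drug ids as row names.
#'   An empty file yields a matrix with zero rows.
#' @export
read_fingerprints <- function(path, format = c("bit-table", "smiles"),
                              fp_bits = 1024) {
  format <- match.arg(format)
  if (format == "smiles") return(read_smiles_fingerprints(path, fp_bits))
  tab <- read_tsv_table(path, c("drug_id", "fingerprint"))
  if (nrow(tab) == 0L)
    return(matrix(integer(0), 0, 0))
  ids <- unname(tab[, "drug_id"])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate drug_id in fingerprint table: ",
         paste(unique(dup), collapse = ", "))
  bits <- tab[, "fingerprint"]
  if (any(grepl("[^01]", bits)))
    stop("fingerprint strings may contain only 0 and 1 (drug ",
         ids[grepl("[^01]", bits)][1L], ")")
  len <- nchar(bits)
  if (length(unique(len)) != 1L) {
    off <- which(len != len[1L])[1L]
    stop(sprintf(
      "ragged fingerprint table: drug %s (line %s) has length %d, expected %d",
      ids[off], rownames(tab)[off], len[off], len[1L]))
  }
  m <- t(vapply(strsplit(bits, "", fixed = TRUE),
                function(ch) as.integer(ch), integer(len[1L])))
  rownames(m) <- ids
  m
}

read_smiles_fingerprints <- function(path, fp_bits) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("SMILES input needs the ChemmineR fingerprinting backend")
  tab <- read_tsv_table(path, c("drug_id", "smiles"))
  if (nrow(tab) == 0L) return(matrix(integer(0), 0, 0))
  ids <- unname(tab[, "drug_id"])
  if (anyDuplicated(ids))
    stop("duplicate drug_id in SMILES table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  smi <- stats::setNames(unname(tab[, "smiles"]), ids)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
  parsed <- ChemmineR::sdfid(sdf)
  ok <- ChemmineR::validSDF(sdf)
  bad <- union(setdiff(ids, parsed), parsed[!ok])
  if (length(bad))
    stop("unparseable SMILES for drug(s): ", paste(bad, collapse = ", "))
  apfreq <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = apfreq)
  descnames <- as.character(apfreq$apfp$AP[seq_len(fp_bits)])
  fp <- ChemmineR::desc2fp(ChemmineR::sdf2ap(sdf),
                           descnames = descnames, type = "matrix")
  storage.mode(fp) <- "integer"
  rownames(fp) <- ids
  fp
}

#' Read a drug-to-target mapping
#'
#' Two-column TSV (`drug_id`, `protein_id`), one pair per line. Duplicate
#' pairs collapse to one; drugs with no rows are absent from the result.
#'
#' @param path TSV file.
#' @return named list of character vectors (target sets, sorted).
#' @export
read_targets <- function(path) {
  tab <- read_tsv_table(path, c("drug_id", "protein_id"))
  if (nrow(tab) == 0L) return(stats::setNames(list(), character(0)))
  lapply(split(unname(tab[, "protein_id"]),
               factor(tab[, "drug_id"], levels = unique(tab[, "drug_id"]))),
         function(p) sort(unique(p)))
}

#' Read an undirected protein-protein interaction network
#'
#' Two-column TSV edge list. Self-loops are dropped (with a message giving
#' their count) and duplicate edges, in either orientation, collapse.
#'
#' @param path TSV file with columns `protein_a`, `protein_b`.
#' @return an undirected [igraph::graph] with protein ids as vertex names.
#' @export
read_ppi <- function(path) {
  tab <- read_tsv_table(path, c("protein_a", "protein_b"))
  if (nrow(tab) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  loops <- tab[, 1L] == tab[, 2L]
  if (any(loops))
    message("read_ppi: dropped ", sum(loops), " self-loop(s)")
  g <- igraph::graph_from_edgelist(tab[, 1:2, drop = FALSE],
                                   directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read per-drug differential expression statistics
#'
#' TSV with columns `drug_id`, `gene_id`, `p_value`, `log_fc`, as produced
#' upstream by a limma-style contrast per drug. The fold-change sign is
#' reduced to -1/+1 (a log fold change of exactly 0 maps to +1). Every
#' drug must cover the same gene universe unless `intersect_genes = TRUE`,
#' in which case the common gene set is used.
#'
#' @param path TSV file.
#' @param intersect_genes restrict to the genes shared by all drugs
#'   instead of requiring identical gene sets.
#' @return list with elements `pvals` and `signs`: numeric matrices with
#'   drugs as rows and genes as columns.
#' @export
read_expression_stats <- function(path, intersect_genes = FALSE) {
  tab <- read_tsv_table(path, c("drug_id", "gene_id", "p_value", "log_fc"))
  if (nrow(tab) == 0L)
    return(list(pvals = matrix(numeric(0), 0, 0),
                signs = matrix(numeric(0), 0, 0)))
  p <- suppressWarnings(as.numeric(tab[, "p_value"]))
  lfc <- suppressWarnings(as.numeric(tab[, "log_fc"]))
  if (anyNA(p) || anyNA(lfc))
    stop("non-numeric p_value or log_fc at line ",
         rownames(tab)[which(is.na(p) | is.na(lfc))[1L]])
  if (any(p <= 0 | p > 1))
    stop("p_value outside (0, 1] at line ",
         rownames(tab)[which(p <= 0 | p > 1)[1L]])
  drug <- unname(tab[, "drug_id"]); gene <- unname(tab[, "gene_id"])
  if (anyDuplicated(paste0(drug, "\r", gene)))
    stop("duplicate (drug_id, gene_id) rows in expression table")
  drugs <- unique(drug)
  genes_by_drug <- split(gene, factor(drug, levels = drugs))
  universe <- sort(unique(gene))
  if (intersect_genes) {
    universe <- sort(Reduce(intersect, genes_by_drug))
    if (length(universe) == 0L)
      stop("no genes shared by all drugs")
  } else {
    for (d in drugs) {
      missing <- setdiff(universe, genes_by_drug[[d]])
      if (length(missing))
        stop(sprintf("inconsistent gene sets: drug %s lacks gene(s) %s", d,
                     paste(utils::head(missing, 5L), collapse = ", ")))
    }
  }
  pv <- matrix(NA_real_, length(drugs), length(universe),
               dimnames = list(drugs, universe))
  sg <- pv
  keep <- gene %in% universe
  idx <- cbind(match(drug[keep], drugs), match(gene[keep], universe))
  pv[idx] <- p[keep]
  sg[idx] <- ifelse(lfc[keep] < 0, -1, 1)
  list(pvals = pv, signs = sg)
}

#' Read ATC level-2 labels
#'
#' Two-column TSV (`drug_id`, `atc2`). Labels must be level-2 codes (one
#' upper-case letter followed by two digits, e.g. `L01`); rows that do not
#' match are rejected with a warning. A drug listed with several codes
#' keeps the first in file order (`multi_atc = "first"`, logged) or is
#' removed (`multi_atc = "drop"`).
#'
#' @param path TSV file.
#' @param multi_atc `"first"` or `"drop"`.
#' @return named character vector, drug id to ATC level-2 code.
#' @export
read_atc <- function(path, multi_atc = c("first", "drop")) {
  multi_atc <- match.arg(multi_atc)
  tab <- read_tsv_table(path, c("drug_id", "atc2"))
  if (nrow(tab) == 0L) return(stats::setNames(character(0), character(0)))
  ok <- grepl("^[A-Z][0-9]{2}$", tab[, "atc2"])
  if (!all(ok)) {
    warning("read_atc: rejected ", sum(!ok),
            " row(s) with malformed ATC level-2 code(s): ",
            paste(utils::head(tab[!ok, "atc2"], 5L), collapse = ", "))
    tab <- tab[ok, , drop = FALSE]
  }
  ids <- tab[, "drug_id"]
  dup <- duplicated(ids)
  if (any(dup)) {
    conflicted <- unique(ids[dup])
    message("read_atc: ", length(conflicted),
            " drug(s) with multiple ATC codes (",
            if (multi_atc == "first") "keeping first" else "dropped", ")")
    if (multi_atc == "first") {
      tab <- tab[!dup, , drop = FALSE]
    } else {
      tab <- tab[!(ids %in% conflicted), , drop = FALSE]
    }
  }
  stats::setNames(unname(tab[, "atc2"]), unname(tab[, "drug_id"]))
}

#' Write / read a dissimilarity matrix as TSV
#'
#' The file has drug ids as both the header row (after a leading
#' `drug_id` cell) and the first column. Values are written with 17
#' significant digits so a write/read round trip is lossless at double
#' precision. On read, asymmetry beyond 1e-12 is an error.
#'
#' @param m a [dissim_matrix] (or plain symmetric labelled matrix).
#' @param path output/input file.
#' @return `read_matrix` returns a [dissim_matrix]; `write_matrix`
#'   invisibly returns `path`.
#' @export
write_matrix <- function(m, path) {
  ids <- rownames(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("drug_id", ids), collapse = "\t"), con)
  body <- vapply(seq_along(ids), function(i)
    paste(c(ids[i], sprintf("%.17g", m[i, ])), collapse = "\t"),
    character(1L))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_matrix
#' @param check_range passed to [dissim_matrix()].
#' @export
read_matrix <- function(path, check_range = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop("matrix file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- fields[[1L]][-1L]
  n <- length(ids)
  if (any(lengths(fields[-1L]) != n + 1L))
    stop("matrix file has ragged rows: ", path)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    if (fields[[i + 1L]][1L] != ids[i])
      stop("matrix row order does not match header in ", path)
    m[i, ] <- as.numeric(fields[[i + 1L]][-1L])
  }
  if (anyNA(m)) stop("non-numeric matrix entries in ", path)
  dissim_matrix(m, check_range = check_range)
}
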