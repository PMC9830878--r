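#' Read a 10x-style sparse count matrix directory
#'
#' Reads the standard \code{filtered_feature_bc_matrix} layout: a Matrix
#' Market \code{matrix.mtx} (genes x cells, as written by Cell Ranger) plus
#' \code{barcodes.tsv} and \code{features.tsv} (or \code{genes.tsv}).
#' Gzipped variants of all three files are accepted. The features file may
#' have one column (id) or three (id, name, type); the first column is the
#' key either way. The matrix is transposed to cells x genes and held sparse.
#'
#' @param path directory containing the three files.
#' @param species species tag recorded on the result (from configuration,
#'   never inferred from identifiers).
#' @param batch optional batch tag.
#' @return A \code{\link{cell_matrix}}.
#' @export
read_count_matrix <- function(path, species = "unknown", batch = NULL) {
  find1 <- function(cands) {
    for (f in cands) {
      p <- file.path(path, f)
      if (file.exists(p)) return(p)
    }
    stop(sprintf("missing file in '%s': expected one of %s", path,
                 paste(cands, collapse = ", ")), call. = FALSE)
  }
  mtx_path <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  bc_path  <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
  ft_path  <- find1(c("features.tsv", "features.tsv.gz",
                      "genes.tsv", "genes.tsv.gz"))
  mm <- Matrix::readMM(mtx_path)
  barcodes <- utils::read.table(bc_path, sep = "\t", header = FALSE,
                                colClasses = "character")[[1]]
  features <- utils::read.table(ft_path, sep = "\t", header = FALSE,
                                colClasses = "character")[[1]]
  if (nrow(mm) != length(features) || ncol(mm) != length(barcodes))
    stop(sprintf(
      "matrix is %d x %d but features/barcodes list %d/%d entries",
      nrow(mm), ncol(mm), length(features), length(barcodes)), call. = FALSE)
  cell_matrix(Matrix::t(mm), cell_ids = barcodes, gene_ids = features,
              species = species, batch = batch)
}

#' Write a \code{cell_matrix} as a 10x-style directory
#'
#' Inverse of \code{\link{read_count_matrix}}: writes \code{matrix.mtx}
#' (genes x cells), \code{barcodes.tsv} and \code{features.tsv}.
#'
#' @param m a \code{cell_matrix}.
#' @param path output directory (created if absent).
#' @return \code{path}, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "cell_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(m$counts), file.path(path, "matrix.mtx"))
  writeLines(cell_ids(m), file.path(path, "barcodes.tsv"))
  writeLines(gene_ids(m), file.path(path, "features.tsv"))
  invisible(path)
}

#' Read OrthoMCL-style ortholog groups
#'
#' Parses the \code{groups.txt} dialect: one group per line,
#' \code{"group_id: species|gene species|gene ..."}. Every listed gene is
#' assigned to exactly one group; a gene appearing in two groups is an
#' integrity error. Genes absent from the file are simply unmapped.
#'
#' @param path path to the groups text file.
#' @return An object of class \code{ortho_group_map}: a named list mapping
#'   group_id to a data.frame with columns \code{species}, \code{gene_id},
#'   plus attribute \code{n_members}.
#' @export
read_ortholog_groups <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  groups <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0)
      stop(sprintf("line %d: missing 'group_id:' prefix", i), call. = FALSE)
    gid <- trimws(substr(ln, 1, colon - 1))
    rest <- trimws(substring(ln, colon + 1))
    if (!nzchar(gid) || !nzchar(rest))
      stop(sprintf("line %d: malformed group line", i), call. = FALSE)
    toks <- strsplit(rest, "[ \t]+")[[1]]
    parts <- strsplit(toks, "|", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad))
      stop(sprintf("line %d: malformed member token '%s'", i,
                   toks[which(bad)[1]]), call. = FALSE)
    groups[[i]] <- data.frame(
      species = vapply(parts, `[`, "", 1),
      gene_id = vapply(parts, `[`, "", 2),
      stringsAsFactors = FALSE)
    ids[[i]] <- gid
  }
  if (anyDuplicated(ids))
    stop(sprintf("duplicated group id '%s'", ids[anyDuplicated(ids)]),
         call. = FALSE)
  names(groups) <- ids
  all_keys <- unlist(lapply(groups, function(g) paste(g$species, g$gene_id,
                                                      sep = "\r")),
                     use.names = FALSE)
  if (anyDuplicated(all_keys)) {
    dup <- all_keys[duplicated(all_keys)][1]
    stop(sprintf("gene '%s' listed in more than one group",
                 sub("\r", "|", dup, fixed = TRUE)), call. = FALSE)
  }
  structure(groups, class = "ortho_group_map",
            n_members = lengths(lapply(groups, `[[`, "gene_id")))
}

#' Write ortholog groups in the \code{groups.txt} dialect
#'
#' @param map an \code{ortho_group_map}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ortholog_groups <- function(map, path) {
  stopifnot(inherits(map, "ortho_group_map"))
  lines <- vapply(names(map), function(gid) {
    g <- map[[gid]]
    paste0(gid, ": ", paste(g$species, g$gene_id, sep = "|", collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.ortho_group_map <- function(x, ...) {
  cat(sprintf("<ortho_group_map> %d groups, %d genes, species: %s\n",
              length(x), sum(attr(x, "n_members")),
              paste(sort(unique(unlist(lapply(x, `[[`, "species")))),
                    collapse = ", ")))
  invisible(x)
}

#' Read a labeled embedding table
#'
#' Headered TSV with a mandatory \code{cell_id} column, a \code{species}
#' column, an optional \code{cluster} column, and coordinate columns (all
#' remaining numeric columns, in file order).
#'
#' @param path TSV file path.
#' @return A \code{\link{labeled_embedding}}.
#' @export
read_embedding <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("cell_id", "species"))
    if (!col %in% names(df))
      stop(sprintf("embedding table needs a '%s' column", col), call. = FALSE)
  coord_cols <- setdiff(names(df), c("cell_id", "species", "cluster"))
  labeled_embedding(df$cell_id, as.matrix(df[coord_cols]), df$species,
                    if ("cluster" %in% names(df)) df$cluster else NULL)
}

#' Write a labeled embedding table
#'
#' @param emb a \code{labeled_embedding}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "labeled_embedding"))
  df <- data.frame(cell_id = emb$cell_ids, emb$coordinates,
                   species = emb$species, check.names = FALSE)
  if (!is.null(emb$cluster)) df$cluster <- emb$cluster
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LCM TPM table
#'
#' TSV with genes as rows (first column \code{gene_id}) and one column per
#' replicate; the header encodes the cell type as \code{"<type>.<rep>"}
#' (everything before the last dot is the type).
#'
#' @param path TSV file path.
#' @return An \code{\link{lcm_profile}}.
#' @export
read_lcm_profile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id")
    stop("first column must be 'gene_id'", call. = FALSE)
  tpm <- as.matrix(df[-1])
  rownames(tpm) <- df$gene_id
  lcm_profile(tpm, sub("\\.[^.]*$", "", colnames(tpm)))
}

#' Write an LCM TPM table
#'
#' @param lcm an \code{lcm_profile}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_lcm_profile <- function(lcm, path) {
  stopifnot(inherits(lcm, "lcm_profile"))
  reps <- stats::ave(seq_along(lcm$cell_type), lcm$cell_type,
                     FUN = seq_along)
  df <- data.frame(gene_id = rownames(lcm$tpm), lcm$tpm, check.names = FALSE)
  names(df)[-1] <- paste(lcm$cell_type, reps, sep = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pseudotime table
#'
#' Headered TSV with columns \code{cell_id}, \code{lineage}, \code{t}.
#'
#' @param path TSV file path.
#' @return A data.frame with those three columns.
#' @export
read_pseudotime <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "lineage", "t")
  if (!all(need %in% names(df)))
    stop("pseudotime table needs columns cell_id, lineage, t", call. = FALSE)
  df[need]
}
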