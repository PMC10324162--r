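# Readers and writers for labeled tab-delimited matrices in the dialect of
# the public gold-standard interaction sets: first row = column labels,
# first column = row labels, tab separated. The distributed adjacency files
# are oriented targets x drugs in some sets; the loader normalizes to
# drugs-as-rows by matching labels against the similarity files.

#' Read a labeled tab-delimited matrix
#'
#' @param path file path.
#' @param role one of `"adjacency"`, `"sim_drugs"`, `"sim_targets"`;
#'   controls validation. Adjacency must be strictly binary; similarity
#'   matrices must be square, symmetric within 1e-6 (symmetrized with a
#'   warning when slightly off), with unit diagonal within 1e-6 and values
#'   in \[0, 1\]. Empty cells in similarity files are read as `NA`
#'   (unobserved).
#' @return list of class `dti_matrix_file` with `values` (numeric matrix
#'   with dimnames), `role`, `path`.
#' @export
read_dti_matrix <- function(path, role = c("adjacency", "sim_drugs",
                                           "sim_targets")) {
  role <- match.arg(role)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           row.names = NULL, na.strings = c("NA", ""),
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L) {
    stop(sprintf("%s: expected row labels plus at least one data column", path),
         call. = FALSE)
  }
  row_labels <- raw[[1]]
  col_labels <- colnames(raw)[-1]
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels)) {
    stop(sprintf("%s: duplicate row or column labels", path), call. = FALSE)
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("%s: non-numeric cell at row '%s', column '%s'",
                 path, row_labels[bad[1, 1]], col_labels[bad[1, 2]]),
         call. = FALSE)
  }
  dimnames(num) <- list(row_labels, col_labels)

  if (role == "adjacency") {
    bad <- which(is.na(num) | !(num %in% c(0, 1)), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("%s: adjacency cell at row '%s', column '%s' is not 0/1",
                   path, row_labels[bad[1, 1]], col_labels[bad[1, 2]]),
           call. = FALSE)
    }
  } else {
    num <- validate_similarity(num, sprintf("%s (%s)", role, path))
    dimnames(num) <- list(row_labels, col_labels)
    if (!identical(row_labels, col_labels)) {
      stop(sprintf("%s: similarity row and column labels differ", path),
           call. = FALSE)
    }
  }
  structure(list(values = num, role = role, path = path),
            class = "dti_matrix_file")
}

#' Write a labeled matrix in the same tab-delimited dialect
#'
#' Numbers are serialized with 10 significant digits, so read/write
#' round-trips are stable.
#'
#' @param values numeric matrix with dimnames (or a `dti_matrix_file`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dti_matrix <- function(values, path) {
  if (inherits(values, "dti_matrix_file")) values <- values$values
  fmt <- matrix(vapply(values, function(v) {
    if (is.na(v)) "" else format(v, digits = 10, scientific = FALSE, trim = TRUE)
  }, character(1)), nrow(values), dimnames = dimnames(values))
  lines <- c(paste(c("id", colnames(values)), collapse = "\t"),
             vapply(seq_len(nrow(values)), function(i) {
               paste(c(rownames(values)[i], fmt[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a network from three matrix files
#'
#' Aligns the three matrices by their labels. If the adjacency rows do not
#' match the drug-similarity labels but its columns do, the adjacency is
#' transposed (the distributed files vary in orientation); the decision is
#' reported. Similarity matrices are reordered to the adjacency label
#' order, so permuted inputs yield the same network.
#'
#' @param adj,sd,st `dti_matrix_file` objects (roles: adjacency, sim_drugs,
#'   sim_targets).
#' @return a [dti_network()]; basic statistics are reported via `message()`.
#' @export
assemble_network <- function(adj, sd, st) {
  stopifnot(inherits(adj, "dti_matrix_file"), adj$role == "adjacency",
            inherits(sd, "dti_matrix_file"), sd$role == "sim_drugs",
            inherits(st, "dti_matrix_file"), st$role == "sim_targets")
  A <- adj$values
  drug_labels <- rownames(sd$values)
  target_labels <- rownames(st$values)
  if (setequal(rownames(A), drug_labels) && setequal(colnames(A), target_labels)) {
    # drugs already on rows
  } else if (setequal(colnames(A), drug_labels) &&
             setequal(rownames(A), target_labels)) {
    message("adjacency oriented targets x drugs; transposed on load")
    A <- t(A)
  } else {
    miss_d <- setdiff(drug_labels, union(rownames(A), colnames(A)))
    extra <- setdiff(union(rownames(A), colnames(A)),
                     union(drug_labels, target_labels))
    stop(sprintf(
      "label mismatch between adjacency and similarity files; missing drug ids: %s; unmatched adjacency ids: %s",
      paste(utils::head(miss_d, 5L), collapse = ", "),
      paste(utils::head(extra, 5L), collapse = ", ")), call. = FALSE)
  }
  net <- dti_network(A,
                     sim_drugs = sd$values[rownames(A), rownames(A)],
                     sim_targets = st$values[colnames(A), colnames(A)],
                     drug_ids = rownames(A), target_ids = colnames(A))
  k <- sum(net$adjacency)
  message(sprintf(
    "loaded network: %d drugs, %d targets, %d interactions, sparsity %.2f%%",
    length(net$drug_ids), length(net$target_ids), k,
    dataset_sparsity(length(net$drug_ids), length(net$target_ids), k)))
  net
}

#' Read a network directly from three file paths
#' @param adjacency,sim_drugs,sim_targets file paths.
#' @return a [dti_network()].
#' @export
read_dti_network <- function(adjacency, sim_drugs, sim_targets) {
  assemble_network(read_dti_matrix(adjacency, "adjacency"),
                   read_dti_matrix(sim_drugs, "sim_drugs"),
                   read_dti_matrix(sim_targets, "sim_targets"))
}

#' Write embedding coordinates as TSV
#'
#' One file per domain: columns `id`, `coord_1` .. `coord_R`.
#'
#' @param emb a [kpe_fit()] result.
#' @param drugs_path,targets_path output paths.
#' @return invisibly, the two paths.
#' @export
write_embedding <- function(emb, drugs_path, targets_path) {
  write_block <- function(X, ids, path) {
    df <- data.frame(id = ids, X, check.names = FALSE)
    utils::write.table(format(df, digits = 10, trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_block(emb$X_d, emb$drug_ids, drugs_path)
  write_block(emb$X_t, emb$target_ids, targets_path)
  invisible(c(drugs_path, targets_path))
}
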