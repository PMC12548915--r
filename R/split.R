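# Butina sphere-exclusion clustering on fingerprint Tanimoto distance, and
# cold-drug / cold-food dataset splits built on whole compound clusters.

#' Tanimoto distance matrix over fingerprint bit sets
#'
#' @param smiles Character vector of SMILES (names, if present, label the
#'   result).
#' @return Symmetric matrix of Tanimoto distances between the compounds'
#'   1024-bit radius-2 fingerprints.
#' @export
tanimoto_distance_matrix <- function(smiles) {
  sets <- lapply(smiles, function(s) compute_substructures(s)$bits)
  n <- length(sets)
  M <- matrix(0, n, N_FP_BITS)
  for (i in seq_len(n)) M[i, sets[[i]] + 1L] <- 1
  inter <- M %*% t(M)
  sizes <- vapply(sets, length, numeric(1))
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  dimnames(d) <- list(names(smiles), names(smiles))
  d
}

#' Butina clustering
#'
#' Sphere-exclusion clustering on Tanimoto distance between 1024-bit
#' radius-2 fingerprints: repeatedly select the unassigned compound with the
#' most unassigned neighbors within the cutoff as a centroid and assign its
#' whole neighborhood to a new cluster, until every compound is assigned.
#' Ties are broken by input order, making the result deterministic.
#'
#' @param smiles Named character vector of SMILES (names are compound ids;
#'   unnamed inputs are labeled by position).
#' @param distance_cutoff Tanimoto distance within which compounds count as
#'   neighbors, in (0, 1).
#' @return Named integer vector: compound id -> cluster id (1-based, in
#'   creation order).
#' @export
butina_clusters <- function(smiles, distance_cutoff = 0.6) {
  stopifnot(length(smiles) >= 1L, distance_cutoff > 0, distance_cutoff < 1)
  ids <- names(smiles) %||% as.character(seq_along(smiles))
  d <- tanimoto_distance_matrix(smiles)
  n <- length(smiles)
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= distance_cutoff))
  assigned <- rep(NA_integer_, n)
  cl <- 0L
  while (anyNA(assigned)) {
    open <- which(is.na(assigned))
    counts <- vapply(open, function(i) sum(is.na(assigned[nbr[[i]]])), integer(1))
    centroid <- open[which.max(counts)]  # first max = input-order tie-break
    cl <- cl + 1L
    members <- nbr[[centroid]][is.na(assigned[nbr[[centroid]]])]
    assigned[unique(c(centroid, members))] <- cl
  }
  names(assigned) <- ids
  assigned
}

#' Cold-compound dataset split
#'
#' Builds a train/validation/test split in which the cold-side compounds
#' (drugs for `cold_drug`, foods for `cold_food`) are Butina-clustered and
#' every cluster is assigned whole to one partition, so no cold-side
#' compound (nor any near neighbor within the cutoff) is shared between
#' partitions.  Clusters are taken largest-first (by number of examples) and
#' greedily assigned to the partition with the largest remaining deficit
#' relative to the target fractions; ties among equal-size clusters are
#' ordered by a seeded draw.
#'
#' @param examples DFI data frame.
#' @param mode `"cold_drug"` or `"cold_food"`.
#' @param fractions Named numeric vector `c(train=, valid=, test=)` summing
#'   to 1.
#' @param distance_cutoff Butina Tanimoto-distance cutoff.
#' @param seed Integer seed for tie-breaking.
#' @return Object of class `split_spec` with `mode`, `cluster_of` (compound
#'   id -> cluster), `partition_of` (cluster -> partition), `fractions`,
#'   `distance_cutoff`, `seed`.
#' @export
cold_split <- function(examples, mode = c("cold_drug", "cold_food"),
                       fractions = c(train = 0.72, valid = 0.06, test = 0.22),
                       distance_cutoff = 0.6, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  if (is.null(names(fractions))) names(fractions) <- c("train", "valid", "test")
  side <- if (mode == "cold_drug") "drug" else "food"
  ids <- examples[[paste0(side, "_id")]]
  sm <- examples[[paste0(side, "_smiles")]]
  uniq <- !duplicated(ids)
  cold_smiles <- stats::setNames(sm[uniq], ids[uniq])
  cluster_of <- butina_clusters(cold_smiles, distance_cutoff)
  n_clusters <- max(cluster_of)
  # examples per cluster
  ex_cluster <- cluster_of[ids]
  w <- tabulate(ex_cluster, nbins = n_clusters)
  set.seed(seed)
  ord <- order(-w, stats::runif(n_clusters))
  part_names <- c("train", "valid", "test")
  if (n_clusters < 3L) {
    stop("fewer than 3 compound clusters; cannot fill three partitions ",
         "(use more data or a smaller distance cutoff)", call. = FALSE)
  }
  total <- nrow(examples)
  assigned <- numeric(3L)
  partition_of <- character(n_clusters)
  for (cl in ord) {
    deficit <- fractions[part_names] * total - assigned
    k <- which.max(deficit)
    partition_of[cl] <- part_names[k]
    assigned[k] <- assigned[k] + w[cl]
  }
  if (any(assigned == 0)) {
    stop("a partition received no examples; use more data, different ",
         "fractions, or a smaller distance cutoff", call. = FALSE)
  }
  structure(list(mode = mode, cluster_of = cluster_of,
                 partition_of = stats::setNames(partition_of, seq_len(n_clusters)),
                 fractions = fractions[part_names],
                 distance_cutoff = distance_cutoff, seed = as.integer(seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %s, %d compounds in %d clusters (cutoff %.2f, seed %d)\n",
              x$mode, length(x$cluster_of), length(x$partition_of),
              x$distance_cutoff, x$seed))
  print(table(x$partition_of[as.character(x$cluster_of)])[c("train", "valid", "test")])
  invisible(x)
}

#' Partition assignment of every example under a split
#'
#' @param split A `split_spec`.
#' @param examples DFI data frame.
#' @return Character vector (`train` / `valid` / `test`) per example row.
#' @export
split_partitions <- function(split, examples) {
  side <- if (split$mode == "cold_drug") "drug_id" else "food_id"
  ids <- examples[[side]]
  unknown <- setdiff(unique(ids), names(split$cluster_of))
  if (length(unknown) > 0L) {
    stop("example cold-side compound(s) absent from split: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  unname(split$partition_of[as.character(split$cluster_of[ids])])
}

#' Audit cold-side leakage of a split
#'
#' @param split A `split_spec`.
#' @param examples DFI data frame.
#' @return Number of cold-side compound ids appearing in more than one
#'   partition (0 for a valid cold split).
#' @export
audit_split_leakage <- function(split, examples) {
  side <- if (split$mode == "cold_drug") "drug_id" else "food_id"
  part <- split_partitions(split, examples)
  tab <- table(examples[[side]], part)
  sum(rowSums(tab > 0) > 1L)
}

#' Write / read a split specification
#'
#' Delimited text with a provenance header (`# key=value` lines for mode,
#' cutoff, seed and fractions) followed by columns `compound_id`,
#' `cluster_id`, `partition`.
#'
#' @param split A `split_spec`.
#' @param path File path.
#' @export
write_split_spec <- function(split, path) {
  hdr <- c(sprintf("# mode=%s", split$mode),
           sprintf("# distance_cutoff=%g", split$distance_cutoff),
           sprintf("# seed=%d", split$seed),
           sprintf("# fractions=%s", paste(split$fractions, collapse = ",")))
  body <- data.frame(compound_id = names(split$cluster_of),
                     cluster_id = unname(split$cluster_of),
                     partition = unname(split$partition_of[as.character(split$cluster_of)]))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(body, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_split_spec
#' @export
read_split_spec <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  get_kv <- function(key) sub(paste0("^# ", key, "="), "", hdr[grepl(paste0("^# ", key, "="), hdr)])
  body <- data.table::fread(text = lines[!grepl("^#", lines)], header = TRUE,
                            data.table = FALSE)
  body$compound_id <- as.character(body$compound_id)
  cluster_of <- stats::setNames(as.integer(body$cluster_id), body$compound_id)
  pdf <- unique(body[, c("cluster_id", "partition")])
  fractions <- as.numeric(strsplit(get_kv("fractions"), ",")[[1]])
  names(fractions) <- c("train", "valid", "test")
  structure(list(mode = get_kv("mode"), cluster_of = cluster_of,
                 partition_of = stats::setNames(pdf$partition, pdf$cluster_id),
                 fractions = fractions,
                 distance_cutoff = as.numeric(get_kv("distance_cutoff")),
                 seed = as.integer(get_kv("seed"))),
            class = "split_spec")
}
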