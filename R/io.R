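#' Write a connectome to disk
#'
#' Two plain-text files per individual: `<id>_adjacency.csv` (dense weight
#' matrix, header = region names, row order = column order) and
#' `<id>_regions.tsv` (columns name, hemisphere, system, volume, x, y, z).
#'
#' @param x A `connectome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_connectome <- function(x, dir) {
  stopifnot(inherits(x, "connectome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  adj <- file.path(dir, paste0(x$individual_id, "_adjacency.csv"))
  met <- file.path(dir, paste0(x$individual_id, "_regions.tsv"))
  utils::write.csv(as.data.frame(x$weights), adj, row.names = FALSE)
  utils::write.table(x$regions, met, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(adjacency = adj, regions = met))
}

#' Read a connectome from disk
#'
#' @param dir Directory holding the two files written by [write_connectome()].
#' @param individual_id Individual label (file prefix).
#' @param age Age in years to attach.
#' @return A `connectome`.
#' @export
read_connectome <- function(dir, individual_id, age = NA_real_) {
  adj <- file.path(dir, paste0(individual_id, "_adjacency.csv"))
  met <- file.path(dir, paste0(individual_id, "_regions.tsv"))
  W <- as.matrix(utils::read.csv(adj, check.names = FALSE))
  regions <- utils::read.delim(met, stringsAsFactors = FALSE)
  connectome(W, regions, age = age, individual_id = individual_id)
}

#' Write a cohort and its manifest
#'
#' Writes each connectome via [write_connectome()] plus a `manifest.tsv` with
#' columns individual_id, age, path.
#'
#' @param cohort Output of [generate_cohort()], or a list of connectomes.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  connectomes <- if (!is.null(cohort$connectomes)) cohort$connectomes else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(connectomes, function(cn) {
    write_connectome(cn, dir)
    data.frame(individual_id = cn$individual_id, age = cn$age, path = dir,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing `manifest.tsv`.
#' @return List with `connectomes` and `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  connectomes <- lapply(seq_len(nrow(manifest)), function(i) {
    read_connectome(manifest$path[i], manifest$individual_id[i],
                    manifest$age[i])
  })
  list(connectomes = connectomes, manifest = manifest)
}

#' Export a connectome as GraphML
#'
#' @param x A `connectome`.
#' @param path Output `.graphml` path.
#' @return Invisibly, the path.
#' @export
export_graphml <- function(x, path) {
  stopifnot(inherits(x, "connectome"))
  g <- igraph::graph_from_adjacency_matrix(x$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  for (col in c("name", "hemisphere", "system", "volume", "x", "y", "z")) {
    g <- igraph::set_vertex_attr(g, col, value = x$regions[[col]])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write / read a synchrony matrix as CSV
#'
#' @param R A `synchrony_matrix`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_synchrony_matrix <- function(R, path) {
  utils::write.csv(as.data.frame(unclass(R)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synchrony_matrix
#' @export
read_synchrony_matrix <- function(path) {
  M <- as.matrix(utils::read.csv(path, check.names = FALSE))
  rownames(M) <- colnames(M)
  class(M) <- c("synchrony_matrix", class(M))
  M
}

#' Write a recorded trajectory as CSV
#'
#' Long-format plain-text persistence of a simulation: one `times` column plus
#' `E_<region>` and `I_<region>` columns.
#'
#' @param trajectory A `wc_trajectory`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "wc_trajectory"))
  nm <- colnames(trajectory$E)
  if (is.null(nm)) nm <- paste0("r", seq_len(ncol(trajectory$E)))
  df <- data.frame(times = trajectory$times,
                   setNames(as.data.frame(trajectory$E), paste0("E_", nm)),
                   setNames(as.data.frame(trajectory$I), paste0("I_", nm)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# strip classes recursively so configs serialize to plain YAML
plainify <- function(x) {
  if (is.list(x)) lapply(unclass(x), plainify) else unclass(x)
}

#' Write a configuration object as YAML
#' @param config Any configuration object of this package.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(plainify(config), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical YAML serialization; used to key resumable pipeline
#' units.
#'
#' @param config A configuration object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(plainify(config), tmp)
  unname(tools::md5sum(tmp))
}
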