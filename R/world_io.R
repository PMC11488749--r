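#' Write an environmental grid as plain text
#'
#' Format: three header lines (`origin_lat`, `origin_lon`,
#' `cell_size_degrees`, each "key value"), then the value matrix row by row,
#' space-separated, latitude rows from the origin upward.
#'
#' @param grid An [env_grid].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_env_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("origin_lat %.10g", grid$origin_lat),
               sprintf("origin_lon %.10g", grid$origin_lon),
               sprintf("cell_size_degrees %.10g", grid$cell_size)), con)
  utils::write.table(grid$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an environmental grid written by [write_env_grid()]
#'
#' @param path Input path.
#' @param name Layer name (default: file base name without extension).
#' @return An [env_grid].
#' @export
read_env_grid <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  hdr <- readLines(path, n = 3L)
  kv <- function(i) as.numeric(strsplit(hdr[i], " ", fixed = TRUE)[[1]][2])
  vals <- as.matrix(utils::read.table(path, skip = 3L))
  dimnames(vals) <- NULL
  env_grid(name, kv(1), kv(2), kv(3), vals)
}

#' Write a synthetic world to a directory of plain-text files
#'
#' Lays out the world the way the pipeline's external inputs look: one FASTA
#' per species x locus under `alignments/`, `occurrences.csv`,
#' `traits.csv` (missing cells empty), one `.grid` file per layer under
#' `grids/`, and the ground truth under `truth/`.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "grids"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (aln in world$alignments)
    write_locus_alignment(
      aln, file.path(dir, "alignments",
                     sprintf("%s_%s.fasta", aln$species, aln$locus)))
  utils::write.csv(world$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(world$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE, na = "")
  for (g in world$env_grids)
    write_env_grid(g, file.path(dir, "grids", paste0(g$name, ".grid")))
  utils::write.csv(world$truth$labels, file.path(dir, "truth", "labels.csv"),
                   row.names = FALSE)
  utils::write.csv(world$truth$lineages,
                   file.path(dir, "truth", "lineages.csv"), row.names = FALSE)
  invisible(dir)
}
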