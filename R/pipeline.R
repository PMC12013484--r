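#' Read a structure file as a point cloud
#'
#' Dispatches on extension: `.pdb` files are parsed with [read_pdb()]
#' (by default keeping only polymer ATOM records), `.pcd` files with
#' [read_pcd()].
#'
#' @param path structure file (`.pdb` or `.pcd`).
#' @param selection for PDB input, passed to
#'   [structure_to_pointcloud()]; default selects non-HETATM atoms.
#' @return a [mol_cloud()].
#' @export
load_structure <- function(path, selection = function(a) !a$hetero) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pcd") return(read_pcd(path))
  if (ext == "pdb") {
    atoms <- read_pdb(path)
    if (!any(!atoms$hetero)) selection <- NULL   # HETATM-only file
    return(structure_to_pointcloud(atoms, selection))
  }
  stop("unsupported structure format: .", ext, " (expected .pdb or .pcd)")
}

#' One-to-many pocket recognition
#'
#' Matches one pocket against every structure in a directory and ranks
#' the structures by correspondence count. Per-protein records
#' (correspondence count, group count, top-group transform and inlier
#' fraction, similarity class) are returned as a data frame and,
#' when `out_dir` is given, written as TSV and JSON together with the
#' fully resolved configuration. Unreadable structures are logged and
#' skipped; the run fails only if no structure parses.
#'
#' @param pocket_path pocket file (`.pdb`, HETATM-free, or `.pcd`).
#' @param protein_dir directory of structure files.
#' @param config a [procv_config()].
#' @param out_dir optional output directory.
#' @return data frame, one row per structure in filename order, with
#'   attributes `best` (the argmax-of-count filename, ties to the first
#'   in filename order) and `config`.
#' @export
run_one_to_many <- function(pocket_path, protein_dir,
                            config = atomic_config(), out_dir = NULL) {
  pocket <- load_structure(pocket_path)
  files <- sort(list.files(protein_dir, pattern = "\\.(pdb|pcd)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stop("no .pdb/.pcd structures found in ", protein_dir)
  rows <- lapply(files, function(f) {
    res <- tryCatch(match_pocket(pocket, load_structure(f), config),
                    error = function(e) {
                      message("skipping ", basename(f), ": ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res))
      return(data.frame(file = basename(f), n_correspondences = NA_integer_,
                        n_groups = NA_integer_, inlier_fraction = NA_real_,
                        rmsd = NA_real_, similarity_class = NA_character_,
                        stringsAsFactors = FALSE))
    top <- if (res$n_groups > 0) res$groups[[1L]] else NULL
    data.frame(
      file = basename(f),
      n_correspondences = as.integer(res$n_correspondences),
      n_groups = res$n_groups,
      inlier_fraction = if (!is.null(top$inlier_fraction))
        top$inlier_fraction else NA_real_,
      rmsd = if (!is.null(top)) top$rmsd else NA_real_,
      similarity_class = classify_similarity(res$n_correspondences,
                                             config$similarity_threshold),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$n_correspondences)))
    stop("no structure in ", protein_dir, " could be processed")
  cnt <- ifelse(is.na(out$n_correspondences), -1L, out$n_correspondences)
  attr(out, "best") <- out$file[which.max(cnt)]
  attr(out, "config") <- config
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(out, file.path(out_dir, "one_to_many.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(pocket = basename(pocket_path),
           best_match = attr(out, "best"),
           results = out,
           config = unclass(config)),
      file.path(out_dir, "one_to_many.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  out
}

#' Noise-robustness sweep
#'
#' Perturbs the protein cloud at each noise level (one independent
#' perturbation per seed) and records the correspondence count of
#' matching the pocket against the perturbed protein, emulating the
#' similarity-grouping-under-noise experiment. Counts are those of
#' the verified similarity groupings (the [match_pocket()] default),
#' so heavily perturbed structures that no longer admit a validated
#' placement contribute zero rather than spurious vote clusters.
#'
#' @param pocket_path pocket file.
#' @param protein_path protein structure file.
#' @param levels ascending noise targets in Angstrom.
#' @param seeds number of replicate seeds (or an explicit integer
#'   vector of seeds).
#' @param config a [procv_config()]; default [atomic_config()].
#' @return data frame with columns `level`, `seed`, `n_correspondences`
#'   and `realized_delta`, plus attribute `means` (per-level mean
#'   counts, in level order).
#' @export
run_noise_sweep <- function(pocket_path, protein_path,
                            levels = c(0, 0.5, 1.0, 1.5),
                            seeds = 20L,
                            config = atomic_config()) {
  if (is.unsorted(levels)) stop("`levels` must be ascending")
  if (length(seeds) == 1L) seeds <- seq_len(seeds)
  pocket <- load_structure(pocket_path)
  protein <- load_structure(protein_path)
  grid <- expand.grid(seed = seeds, level = levels)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    lv <- grid$level[r]; sd <- grid$seed[r]
    pert <- perturb_cloud(protein,
                          noise_spec(lv, seed = sd + 7919L * match(lv, levels)))
    res <- match_pocket(pocket, pert, config)
    data.frame(level = lv, seed = sd,
               n_correspondences = as.integer(res$n_correspondences),
               realized_delta = compute_delta(protein, pert))
  })
  out <- do.call(rbind, rows)
  means <- vapply(levels, function(lv)
    mean(out$n_correspondences[out$level == lv]), numeric(1))
  names(means) <- as.character(levels)
  attr(out, "means") <- means
  attr(out, "config") <- config
  out
}
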