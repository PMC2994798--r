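#' Save and load trained models
#'
#' A model directory holds the training configuration, the pseudo-sequence
#' table, the fold assignment (for cross-validated models) and every
#' network in the flat text format of [write_network()].  Loading pools
#' all networks into one prediction ensemble.
#'
#' @param model An `mhc2_ensemble` or `mhc2_cv`.
#' @param dir Model directory (created if needed).
#' @return `write_model()` returns `dir` invisibly; `read_model()` an
#'   `mhc2_ensemble`.
#' @export
write_model <- function(model, dir) {
  if (inherits(model, "mhc2_cv")) {
    folds <- model$fold
    model_ens <- pooled_ensemble(model)
  } else {
    folds <- NULL
    model_ens <- model
  }
  stopifnot(inherits(model_ens, "mhc2_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model_ens$config
  scal <- setdiff(names(cfg), "schemes")
  writeLines(c(paste("schemes", paste(cfg$schemes, collapse = ",")),
               paste(scal, vapply(cfg[scal], function(v)
                 sprintf("%.17g", as.numeric(v)), ""))),
             file.path(dir, "config.txt"))
  writeLines(paste(names(model_ens$pseudo), model_ens$pseudo),
             file.path(dir, "pseudo.txt"))
  if (!is.null(folds))
    writeLines(as.character(folds), file.path(dir, "folds.txt"))
  for (i in seq_along(model_ens$networks))
    write_network(model_ens$networks[[i]],
                  file.path(dir, sprintf("network-%03d.txt", i)))
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  cfg_lines <- strsplit(readLines(file.path(dir, "config.txt")), " ")
  vals <- setNames(lapply(cfg_lines, `[`, -1L),
                   vapply(cfg_lines, `[`, "", 1L))
  int_fields <- c("n_cycles", "n_seeds", "n_hidden", "n_folds",
                  "master_seed", "pfr_cap")
  args <- lapply(setdiff(names(vals), "schemes"), function(k) {
    v <- as.numeric(vals[[k]])
    if (k %in% int_fields) as.integer(v) else v
  })
  names(args) <- setdiff(names(vals), "schemes")
  args$schemes <- strsplit(vals$schemes, ",")[[1]]
  cfg <- do.call(train_config, args)
  pseudo <- read_pseudosequences(file.path(dir, "pseudo.txt"))
  files <- sort(list.files(dir, pattern = "^network-\\d+\\.txt$",
                           full.names = TRUE))
  if (!length(files)) stop("no network files in ", dir)
  new_ensemble(lapply(files, read_network), cfg, pseudo)
}
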