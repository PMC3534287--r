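# Internal helpers.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Write lines atomically: to a temp file in the target directory, then rename.
atomic_writelines <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("failed to write ", path)
  }
  invisible(path)
}

# Stable hash of a configuration list (md5 of its deparsed form).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

# Versioned output header for CLI artifacts.
output_header <- function(subcommand, seed = NA, config = list()) {
  ver <- tryCatch(as.character(utils::packageVersion("serpintools")),
                  error = function(e) "dev")
  c(paste0("# serpintools v", ver, " | subcommand=", subcommand,
           " | seed=", seed, " | config=", config_hash(config)))
}
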