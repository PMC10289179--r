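#' Read a pipeline configuration file
#'
#' Reads a YAML document with optional blocks `phantom`, `enhance`, `train`,
#' `refine`, `fuse` and `loop`; each block's keys override the corresponding
#' constructor's defaults. Unknown keys are rejected.
#'
#' @param path Path to a YAML config file.
#' @return List with elements `phantom` ([phantom_config()]) and `loop`
#'   ([loop_config()] carrying the other parameter blocks).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(ctor, args) {
    args <- args %||% list()
    known <- names(formals(ctor))
    bad <- setdiff(names(args), known)
    if (length(bad))
      stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    do.call(ctor, args)
  }
  loop_args <- cfg$loop %||% list()
  loop_args$enhance <- build(enhancer_params, cfg$enhance)
  loop_args$train <- build(train_config, cfg$train)
  loop_args$refine <- build(grow_params, cfg$refine)
  loop_args$fuse <- build(fusion_params, cfg$fuse)
  list(phantom = build(phantom_config, cfg$phantom),
       loop = build(loop_config, loop_args))
}
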