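# Single-file model checkpoints: JSON container with a header (shapes,
# normalization constants, package version) and the named parameter arrays.

component_to_list <- function(m) {
  if (is.null(m)) return(NULL)
  out <- lapply(param_names(m), function(nm) {
    list(dim = dim(m[[nm]]) %||% length(m[[nm]]), data = as.vector(m[[nm]]))
  })
  names(out) <- param_names(m)
  meta <- m[setdiff(names(m), c(param_names(m), "colmap1", "colmap2"))]
  list(class = class(m), params = out, meta = meta)
}

component_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  m <- l$meta
  for (nm in names(l$params)) {
    p <- l$params[[nm]]
    v <- as.numeric(unlist(p$data))
    d <- unlist(p$dim)
    m[[nm]] <- if (length(d) > 1L) array(v, d) else v
  }
  int_fields <- intersect(names(m), c("bands", "patch_size", "kernel1",
                                      "kernel2", "filters1", "filters2",
                                      "o1", "o2", "embed_dim", "n_classes"))
  for (nm in int_fields) m[[nm]] <- as.integer(m[[nm]])
  if (!is.null(m$norm)) {
    m$norm <- lapply(m$norm, function(v) as.numeric(unlist(v)))
  }
  if ("embedding_params" %in% l$class) {
    m$colmap1 <- im2col_map(m$patch_size, m$bands, m$kernel1)
    m$colmap2 <- im2col_map(m$o1, m$filters1, m$kernel2)
  }
  class(m) <- unlist(l$class)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a model suite to a single-file JSON checkpoint
#'
#' @param suite a `model_suite` (or a list with any of G_s, G_t, C_s, C_t,
#'   D).
#' @param path output ".json" path.
#' @return `path`, invisibly.
#' @export
save_model_suite <- function(suite, path) {
  payload <- list(
    header = list(container = "seadapt-model-suite", version = 1L,
                  package_version =
                    as.character(utils::packageVersion("seadapt"))),
    components = lapply(suite[c("G_s", "G_t", "C_s", "C_t", "D")],
                        component_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model suite checkpoint
#'
#' @param path checkpoint path written by [save_model_suite()].
#' @return a `model_suite`.
#' @export
load_model_suite <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(payload$header$container, "seadapt-model-suite")) {
    stop("not a model-suite checkpoint: ", path, call. = FALSE)
  }
  comp <- lapply(payload$components, component_from_list)
  model_suite(comp$G_s, comp$G_t, comp$C_s, comp$C_t, comp$D)
}
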