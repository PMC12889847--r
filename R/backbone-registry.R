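#' Register a feature-backbone adapter
#'
#' Real pretrained backbones are user-supplied: an adapter is any function
#' taking a stimulus (path, raw bytes, or array — the adapter's concern) and
#' returning a [token_grid]. Registering it by name makes it addressable
#' from scripts and the CLI config; no weights are ever bundled with the
#' package. Metadata (e.g. which layer or token variant the adapter
#' extracts) travels with the entry.
#'
#' @param name adapter name.
#' @param fn function `(stimulus, ...) -> token_grid`.
#' @param metadata optional list describing the backbone (architecture,
#'   layer, token variant, feature dim).
#' @return `register_backbone` invisibly returns `name`; `get_backbone`
#'   returns the entry (`fn`, `metadata`); `list_backbones` the registered
#'   names.
#' @examples
#' register_backbone("toy8", function(x, ...) toy_backbone(x, c(3, 3), 8),
#'                   metadata = list(d = 8))
#' grid <- get_backbone("toy8")$fn(rnorm(5))
#' @export
register_backbone <- function(name, fn, metadata = list()) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  .backbones[[name]] <- list(fn = fn, metadata = metadata)
  invisible(name)
}

#' @rdname register_backbone
#' @export
get_backbone <- function(name) {
  if (is.null(.backbones[[name]]))
    stop(sprintf("get_backbone: no adapter '%s' (registered: %s)", name,
                 paste(names(.backbones), collapse = ", ")))
  .backbones[[name]]
}

#' @rdname register_backbone
#' @export
list_backbones <- function() names(.backbones)

.backbones <- new.env(parent = emptyenv())
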