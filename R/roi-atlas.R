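#' ROI atlas: vertex-to-region assignment
#'
#' Maps each cortical-surface vertex to a hemisphere (`"LH"` or `"RH"`) and a
#' region-of-interest label. Vertices outside any labeled region carry the
#' reserved label `"unlabeled"`, so that the binary masks derived from the
#' atlas always partition the vertex set.
#'
#' @param vertex_id integer vector of vertex identifiers (unique).
#' @param hemisphere character vector, one of `"LH"`, `"RH"` per vertex.
#' @param roi_label character vector of region labels per vertex.
#' @return An object of class `roi_atlas` with fields `vertex_id`,
#'   `hemisphere`, `roi_label` and a derived `roi_index` mapping
#'   `"<hemisphere>/<roi>"` to vertex positions.
#' @export
roi_atlas <- function(vertex_id, hemisphere, roi_label) {
  vertex_id <- as.integer(vertex_id)
  hemisphere <- as.character(hemisphere)
  roi_label <- as.character(roi_label)
  n <- length(vertex_id)
  if (length(hemisphere) != n || length(roi_label) != n)
    stop("roi_atlas: field lengths differ")
  if (anyDuplicated(vertex_id)) stop("roi_atlas: duplicate vertex ids")
  if (!all(hemisphere %in% c("LH", "RH")))
    stop("roi_atlas: hemisphere must be 'LH' or 'RH'")
  key <- paste(hemisphere, roi_label, sep = "/")
  roi_index <- split(seq_len(n), key)
  roi_index <- lapply(roi_index, sort)
  structure(list(vertex_id = vertex_id, hemisphere = hemisphere,
                 roi_label = roi_label, roi_index = roi_index),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("<roi_atlas: %d vertices, %d (hemisphere, ROI) groups>\n",
              length(x$vertex_id), length(x$roi_index)))
  invisible(x)
}

#' Read / write an ROI atlas as tab-separated text
#'
#' The on-disk format is a UTF-8 TSV with header columns `vertex_id`,
#' `hemisphere`, `roi_label`.
#'
#' @param path file path.
#' @return `read_roi_atlas` returns an [roi_atlas]; `write_roi_atlas`
#'   invisibly returns `path`.
#' @export
read_roi_atlas <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("vertex_id", "hemisphere", "roi_label")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("read_roi_atlas: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  roi_atlas(tab$vertex_id, tab$hemisphere, tab$roi_label)
}

#' @rdname read_roi_atlas
#' @param atlas an [roi_atlas].
#' @export
write_roi_atlas <- function(atlas, path) {
  tab <- data.frame(vertex_id = atlas$vertex_id,
                    hemisphere = atlas$hemisphere,
                    roi_label = atlas$roi_label)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the binary readout masks of an atlas
#'
#' At `granularity = "roi"` one mask is produced per (hemisphere, ROI) group
#' present in the atlas (including `"unlabeled"` if any vertex carries it); at
#' `granularity = "vertex"` one singleton mask per vertex. Masks within a
#' hemisphere are pairwise disjoint and sum to the indicator of that
#' hemisphere's vertices, so combining masked per-query readouts reconstructs
#' every vertex exactly once.
#'
#' @param atlas an [roi_atlas].
#' @param granularity `"roi"` or `"vertex"` — the unit of routing.
#' @return A named list of logical vectors (one per query, over all atlas
#'   vertices), ordered LH before RH and alphabetically by ROI within a
#'   hemisphere (`"unlabeled"` last); at vertex granularity, atlas order.
#' @export
build_masks <- function(atlas, granularity = c("roi", "vertex")) {
  granularity <- match.arg(granularity)
  n <- length(atlas$vertex_id)
  if (granularity == "vertex") {
    masks <- lapply(seq_len(n), function(i) {
      m <- logical(n); m[i] <- TRUE; m
    })
    names(masks) <- sprintf("%s/v%d", atlas$hemisphere, atlas$vertex_id)
    return(masks)
  }
  keys <- names(atlas$roi_index)
  hemi <- sub("/.*$", "", keys)
  roi <- sub("^[^/]*/", "", keys)
  ord <- order(factor(hemi, c("LH", "RH")), roi == "unlabeled", roi)
  keys <- keys[ord]
  masks <- lapply(keys, function(k) {
    m <- logical(n); m[atlas$roi_index[[k]]] <- TRUE; m
  })
  names(masks) <- keys
  masks
}

# Owner vector: for masks that partition the vertex set, the index of the
# unique query whose mask contains each vertex.
mask_owner <- function(masks) {
  n <- length(masks[[1]])
  owner <- integer(n)
  for (q in seq_along(masks)) {
    idx <- which(masks[[q]])
    if (any(owner[idx] != 0L)) stop("mask_owner: overlapping masks")
    owner[idx] <- q
  }
  if (any(owner == 0L)) stop("mask_owner: masks do not cover all vertices")
  owner
}

#' Category-selectivity clusters for the NSD ROI vocabulary
#'
#' The standard grouping of the 24 labeled visual ROIs into five selectivity
#' clusters: early retinotopic, body-, face-, place- and word-selective.
#' Used by [roi_summary()] to aggregate accuracies; the synthetic atlas uses
#' the same vocabulary.
#'
#' @return named character vector mapping ROI label to cluster.
#' @export
nsd_roi_clusters <- function() {
  c("V1v" = "early", "V1d" = "early", "V2v" = "early", "V2d" = "early",
    "V3v" = "early", "V3d" = "early", "hV4" = "early",
    "EBA" = "body", "FBA-1" = "body", "FBA-2" = "body", "mTL-bodies" = "body",
    "OFA" = "face", "FFA-1" = "face", "FFA-2" = "face",
    "mTL-faces" = "face", "aTL-faces" = "face",
    "OPA" = "place", "PPA" = "place", "RSC" = "place",
    "OWFA" = "word", "VWFA-1" = "word", "VWFA-2" = "word",
    "mfs-words" = "word", "mTL-words" = "word")
}
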