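#' Write a frame set to disk
#'
#' Writes each frame as a PNG into a per-category subfolder (`B/`, `I/`,
#' `S/`, `U/`; unlabeled sets go into `frames/`) and a two-column
#' `manifest.csv` (filename, category) next to them.
#'
#' @param frames a `frame_set`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame.
#' @export
write_frame_set <- function(frames, dir) {
  .assert(inherits(frames, "frame_set"), "frames must be a frame_set")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- if (is.null(frames$labels)) rep("frames", length(frames$images))
            else as.character(frames$labels)
  files <- character(length(frames$images))
  for (i in seq_along(frames$images)) {
    sub <- file.path(dir, labels[i])
    dir.create(sub, showWarnings = FALSE)
    files[i] <- file.path(labels[i], paste0(frames$ids[i], ".png"))
    png::writePNG(frames$images[[i]] / 255, file.path(dir, files[i]))
  }
  manifest <- data.frame(filename = files, category = labels)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a frame set from disk
#'
#' Reads PNG/JPEG frames from a folder. If `manifest.csv` exists it gives
#' filenames and categories; otherwise class subfolders (or a flat
#' folder, unlabeled) are scanned.
#'
#' @param dir input directory.
#' @return a `frame_set`.
#' @export
read_frame_set <- function(dir) {
  .assert(dir.exists(dir), paste("no such directory:", dir))
  man_path <- file.path(dir, "manifest.csv")
  if (file.exists(man_path)) {
    man <- read.csv(man_path, stringsAsFactors = FALSE)
    files <- man$filename
    labels <- man$category
  } else {
    files <- list.files(dir, pattern = "\\.(png|jpg|jpeg)$", recursive = TRUE,
                        ignore.case = TRUE)
    .assert(length(files) > 0, "no images found")
    parts <- dirname(files)
    labels <- ifelse(parts == ".", NA_character_, parts)
  }
  images <- lapply(files, function(f) {
    im <- png::readPNG(file.path(dir, f))
    if (length(dim(im)) == 2) im <- array(rep(im, 3), c(dim(im), 3))
    array(as.integer(round(im[, , 1:3] * 255)), c(dim(im)[1:2], 3))
  })
  labs <- if (all(is.na(labels))) NULL
          else factor(labels, levels = c(FRAME_CATEGORIES,
                                         setdiff(unique(labels),
                                                 FRAME_CATEGORIES)))
  structure(list(images = images,
                 labels = labs,
                 ids = tools::file_path_sans_ext(basename(files))),
            class = "frame_set")
}

#' Write / read an embedding or projection matrix
#'
#' Tab-delimited numeric matrix with a one-line `#`-prefixed header naming
#' the backend (or reduction method) for provenance; row names are frame
#' ids.
#'
#' @param x a `frame_embedding` or `frame_projection`.
#' @param path file path.
#' @return `write_embedding` returns `path` invisibly; `read_embedding`
#'   returns a `frame_embedding`.
#' @export
write_embedding <- function(x, path) {
  tag <- if (inherits(x, "frame_projection"))
    paste0("method=", x$method) else x$backend_tag
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", tag), con)
  utils::write.table(x$values, con, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  first <- readLines(path, n = 1)
  tag <- if (startsWith(first, "# ")) sub("^# ", "", first) else "file"
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           row.names = 1)
  as_embedding(as.matrix(tab), tag = tag)
}

#' Write cluster labels / label mapping
#'
#' @param clusters a `cluster_result`.
#' @param mapping a `label_mapping`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_labels <- function(clusters, path) {
  write.csv(data.frame(frame_id = clusters$frame_ids,
                       cluster_id = clusters$labels),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_labels
#' @export
write_label_mapping <- function(mapping, path) {
  jsonlite::write_json(list(map = as.list(mapping$map),
                            total_intersection = mapping$total_intersection,
                            mode = mapping$mode),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
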