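#' Write an extended-XYZ trajectory
#'
#' One block per frame: bead count, a comment line carrying the box as
#' `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"`, then `type x y z` per bead.
#'
#' @param x a `dpd_state` or a list of frames (each with `pos`, `box`).
#' @param path output file.
#' @param type bead type labels (required for plain frames).
#' @export
write_xyz <- function(x, path, type = NULL) {
  frames <- if (inherits(x, "dpd_state")) {
    type <- x$type
    list(list(pos = x$pos, box = x$box))
  } else x
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$pos)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3',
      fr$box[1], fr$box[2], fr$box[3]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", type,
                       fr$pos[, 1], fr$pos[, 2], fr$pos[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' @param path file written by [write_xyz()] (or compatible).
#' @return list of frames, each with `pos`, `box` and `type`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    lat <- regmatches(lines[i + 1],
                      regexpr('Lattice="[^"]*"', lines[i + 1]))
    nums <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), " +")[[1]])
    box <- nums[c(1, 5, 9)]
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), " +")
    type <- vapply(rows, `[[`, character(1), 1)
    pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- list(pos = pos, box = box, type = type)
    i <- i + 2 + n
  }
  frames
}

#' Write a per-frame metrics table as tab-separated text
#'
#' @param df a data.frame.
#' @param path output file.
#' @export
write_metrics <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
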