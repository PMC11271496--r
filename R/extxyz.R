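#' Read an extended-XYZ file
#'
#' Parses extended XYZ (`Lattice="..."`,
#' `Properties=species:S:1:pos:R:3[:forces:R:3]`, `energy=...`, `pbc=...`)
#' into a [configuration_set()]. The parser is whitespace-tolerant; the
#' energy key is `energy` and the force columns `forces`, matching the
#' writer. A malformed frame raises an error naming the frame index.
#'
#' @param path file to read.
#' @param label backend label to attach to energies/forces found in the file
#'   (default `"reference"`).
#' @return a [configuration_set()].
#' @seealso [write_extxyz()]
#' @export
read_extxyz <- function(path, label = "reference") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  configs <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L) {
      stop("frame ", frame, ": malformed atom-count header '", lines[i], "'")
    }
    if (i + 1L + nat > length(lines) + 0L && i + 1L > length(lines)) {
      stop("frame ", frame, ": truncated (missing comment line)")
    }
    comment <- lines[i + 1L]
    body_end <- i + 1L + nat
    if (body_end > length(lines)) {
      stop("frame ", frame, ": declares ", nat, " atoms but only ",
           length(lines) - i - 1L, " atom lines remain")
    }
    body <- lines[(i + 2L):body_end]
    kv <- parse_extxyz_comment(comment)
    props <- parse_extxyz_properties(kv[["Properties"]] %||% "species:S:1:pos:R:3")
    ncol_needed <- sum(vapply(props, function(p) p$count, integer(1)))
    toks <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(toks, length, integer(1)) < ncol_needed)
    if (length(bad)) {
      stop("frame ", frame, ": atom line ", bad[1], " has fewer than ",
           ncol_needed, " fields")
    }
    tokmat <- t(vapply(toks, function(tt) tt[seq_len(ncol_needed)],
                       character(ncol_needed)))
    if (nat == 1L) tokmat <- matrix(tokmat, nrow = 1L)
    col <- 1L
    species <- NULL; pos <- NULL; forces <- NULL
    for (p in props) {
      cols <- col:(col + p$count - 1L)
      if (p$name == "species") {
        species <- tokmat[, cols[1]]
      } else if (p$name == "pos") {
        pos <- matrix(suppressWarnings(as.numeric(tokmat[, cols])), ncol = 3L)
      } else if (p$name == "forces") {
        forces <- matrix(suppressWarnings(as.numeric(tokmat[, cols])), ncol = 3L)
      }
      col <- col + p$count
    }
    if (is.null(species) || is.null(pos)) {
      stop("frame ", frame, ": Properties must include species and pos")
    }
    if (anyNA(pos)) stop("frame ", frame, ": non-numeric coordinate field")
    cell <- NULL; periodic <- FALSE
    if (!is.null(kv[["Lattice"]])) {
      lat <- as.numeric(strsplit(trimws(kv[["Lattice"]]), "[[:space:]]+")[[1]])
      if (length(lat) != 9L || anyNA(lat)) {
        stop("frame ", frame, ": malformed Lattice entry")
      }
      cell <- matrix(lat, nrow = 3L, byrow = TRUE)
    }
    if (!is.null(kv[["pbc"]])) {
      periodic <- any(grepl("T", strsplit(kv[["pbc"]], "[[:space:]]+")[[1]],
                            fixed = TRUE))
    } else if (!is.null(cell)) {
      periodic <- TRUE
    }
    energy <- if (!is.null(kv[["energy"]])) as.numeric(kv[["energy"]]) else NULL
    lab <- if (!is.null(energy) || !is.null(forces)) label else NULL
    configs[[frame]] <- configuration(
      species = species, positions = pos, cell = cell, periodic = periodic,
      energy = energy, forces = forces, label = lab
    )
    i <- body_end + 1L
  }
  configuration_set(configs, name = basename(path),
                    log = paste("read from", path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split an extxyz comment line into key=value pairs, honouring quotes.
parse_extxyz_comment <- function(line) {
  kv <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("([^"]*)"|[^" ]+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1L) return(kv)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (j in seq_along(starts)) {
    piece <- substr(line, starts[j], starts[j] + lens[j] - 1L)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- substr(piece, 1L, eq - 1L)
    val <- substr(piece, eq + 1L, nchar(piece))
    val <- gsub('^"|"$', "", val)
    kv[[key]] <- val
  }
  kv
}

parse_extxyz_properties <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) %% 3L != 0L) stop("malformed Properties spec: ", spec)
  lapply(seq(1L, length(parts), by = 3L), function(j) {
    list(name = parts[j], type = parts[j + 1L],
         count = as.integer(parts[j + 2L]))
  })
}

#' Write configurations as extended XYZ
#'
#' Round trips with [read_extxyz()]: species order, coordinates (to better
#' than 1e-8 Angstrom), energies, forces, lattice and periodicity are all
#' preserved.
#'
#' @param set a [configuration_set()] or single [configuration()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(set, path) {
  if (inherits(set, "configuration")) set <- configuration_set(list(set))
  stopifnot(inherits(set, "configuration_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in set$configs) {
    n <- n_atoms(cf)
    props <- "species:S:1:pos:R:3"
    if (!is.null(cf$forces)) props <- paste0(props, ":forces:R:3")
    fields <- sprintf("Properties=%s", props)
    if (!is.null(cf$cell)) {
      fields <- c(fields, sprintf('Lattice="%s"',
                                  paste(format_num(t(cf$cell)), collapse = " ")))
      fields <- c(fields, sprintf('pbc="%s"',
                                  if (cf$periodic) "T T T" else "F F F"))
    }
    if (!is.null(cf$energy)) {
      fields <- c(fields, sprintf("energy=%s", format_num(cf$energy)))
    }
    writeLines(as.character(n), con)
    writeLines(paste(fields, collapse = " "), con)
    mat <- format_num(cf$positions)
    dim(mat) <- dim(cf$positions)
    lines <- paste(cf$species, mat[, 1], mat[, 2], mat[, 3])
    if (!is.null(cf$forces)) {
      fm <- format_num(cf$forces)
      dim(fm) <- dim(cf$forces)
      lines <- paste(lines, fm[, 1], fm[, 2], fm[, 3])
    }
    writeLines(lines, con)
  }
  invisible(path)
}

format_num <- function(x) formatC(x, format = "g", digits = 17)
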