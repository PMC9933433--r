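# Reading and writing trajectories (extended-XYZ) and APT label sets.
#
# Extended-XYZ is the canonical geometry format here: per-frame comment lines
# carry Lattice="..." (9 numbers, row-major lattice vectors), a Properties
# descriptor (species:S:1:pos:R:3 with an optional vel:R:3 column block) and an
# optional pbc="T T T" flag. The APT container is a self-describing plain-text
# format storing geometry, split labels and 9 floats per atom at full double
# precision, because no community standard exists for per-atom tensor labels.

# parse the key=value fields of an extended-XYZ comment line
.parse_xyz_comment <- function(line) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("([^"]*)"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  starts <- as.integer(m); lens <- attr(m, "match.length")
  for (k in seq_along(starts)) {
    tok <- substr(line, starts[k], starts[k] + lens[k] - 1L)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1L, eq - 1L)
    val <- substr(tok, eq + 1L, nchar(tok))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

# decode a Properties descriptor into a data.frame of (name, type, ncol)
.parse_properties <- function(prop) {
  parts <- strsplit(prop, ":", fixed = TRUE)[[1]]
  .stop_if(length(parts) %% 3 != 0, "malformed Properties descriptor: ", prop)
  n <- length(parts) / 3
  data.frame(name = parts[3 * seq_len(n) - 2],
             type = parts[3 * seq_len(n) - 1],
             ncol = as.integer(parts[3 * seq_len(n)]),
             stringsAsFactors = FALSE)
}

#' Read an extended-XYZ trajectory
#'
#' Parses a (possibly multi-frame) extended-XYZ file into a
#' \linkS4class{Trajectory}. Velocities are populated when a \code{vel:R:3}
#' property block is present. All frames must share atom count and species
#' ordering; a frame violating this raises a validation error naming the
#' frame index.
#'
#' @param path file path.
#' @param dt timestep between frames in fs.
#' @return a \linkS4class{Trajectory}.
#' @seealso \code{\link{writeTrajectory}}
#' @export
readTrajectory <- function(path, dt) {
  lines <- readLines(path)
  frames <- list(); vels <- list(); haveVel <- FALSE
  i <- 1L; fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    fidx <- fidx + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    .stop_if(is.na(nat) || nat <= 0L,
             sprintf("frame %d: malformed atom-count line '%s'",
                     fidx, lines[i]))
    .stop_if(i + 1L + nat > length(lines),
             sprintf("frame %d: truncated (expected %d atom lines)",
                     fidx, nat))
    hdr <- .parse_xyz_comment(lines[i + 1L])
    prop <- if (!is.null(hdr$Properties)) .parse_properties(hdr$Properties)
            else data.frame(name = c("species", "pos"), type = c("S", "R"),
                            ncol = c(1L, 3L), stringsAsFactors = FALSE)
    .stop_if(!all(c("species", "pos") %in% prop$name),
             sprintf("frame %d: Properties must include species and pos", fidx))
    cell <- NULL; pbc <- c(FALSE, FALSE, FALSE)
    if (!is.null(hdr$Lattice)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(hdr$Lattice),
                                                "\\s+")[[1]]))
      .stop_if(length(v) != 9L || any(is.na(v)),
               sprintf("frame %d: malformed Lattice field", fidx))
      cell <- matrix(v, 3, 3, byrow = TRUE)
      pbc <- c(TRUE, TRUE, TRUE)
    }
    if (!is.null(hdr$pbc)) {
      p <- strsplit(trimws(hdr$pbc), "\\s+")[[1]]
      pbc <- toupper(p) %in% c("T", "TRUE", "1")
      .stop_if(length(pbc) != 3L,
               sprintf("frame %d: malformed pbc field", fidx))
    }
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    ncols <- sum(prop$ncol)
    bad <- which(lengths(toks) < ncols)
    .stop_if(length(bad) > 0L,
             sprintf("frame %d: atom line %d has %d fields, expected %d",
                     fidx, bad[1], lengths(toks)[bad[1]], ncols))
    tokm <- do.call(rbind, lapply(toks, `[`, seq_len(ncols)))
    off <- 0L; sp <- NULL; pos <- NULL; vel <- NULL
    for (k in seq_len(nrow(prop))) {
      cols <- (off + 1L):(off + prop$ncol[k])
      if (prop$name[k] == "species") sp <- tokm[, cols]
      if (prop$name[k] == "pos") {
        pos <- matrix(as.numeric(tokm[, cols]), nat, 3)
        .stop_if(any(is.na(pos)),
                 sprintf("frame %d: non-numeric position entry", fidx))
      }
      if (prop$name[k] == "vel") {
        vel <- matrix(as.numeric(tokm[, cols]), nat, 3)
        .stop_if(any(is.na(vel)),
                 sprintf("frame %d: non-numeric velocity entry", fidx))
      }
      off <- off + prop$ncol[k]
    }
    cfg <- atomicConfiguration(sp, pos, cell = cell, pbc = pbc,
                               id = sprintf("frame%06d", fidx))
    if (fidx > 1L && !identical(species(cfg), species(frames[[1L]])))
      stop(sprintf(
        "frame %d: atom count or species ordering differs from frame 1",
        fidx), call. = FALSE)
    frames[[fidx]] <- cfg
    if (!is.null(vel)) { haveVel <- TRUE; vels[[fidx]] <- vel }
    else vels[fidx] <- list(NULL)
    i <- i + 2L + nat
  }
  .stop_if(fidx == 0L, "no frames found in ", path)
  if (haveVel) {
    .stop_if(any(vapply(vels, is.null, logical(1))),
             "velocities present in some frames but not all")
  } else vels <- list()
  trajectory(frames, dt = dt, velocities = vels)
}

#' Write a Trajectory (or a single configuration) to extended-XYZ
#'
#' Numbers are written with 17 significant digits so that a write/read round
#' trip reproduces every double bit for bit.
#'
#' @param x a \linkS4class{Trajectory} or \linkS4class{AtomicConfiguration}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(x, path) {
  if (is(x, "AtomicConfiguration"))
    x <- trajectory(list(x), dt = 1)
  stopifnot(is(x, "Trajectory"))
  con <- file(path, "w"); on.exit(close(con))
  hasV <- hasVelocities(x)
  for (k in seq_len(nFrames(x))) {
    f <- x@frames[[k]]
    n <- nAtoms(f)
    hdr <- character()
    if (!is.null(f@cell))
      hdr <- c(hdr, sprintf('Lattice="%s"',
                            paste(.fmt_num(t(f@cell)), collapse = " ")))
    hdr <- c(hdr, paste0("Properties=species:S:1:pos:R:3",
                         if (hasV) ":vel:R:3" else ""))
    hdr <- c(hdr, sprintf('pbc="%s"',
                          paste(ifelse(f@pbc, "T", "F"), collapse = " ")))
    writeLines(as.character(n), con)
    writeLines(paste(hdr, collapse = " "), con)
    poss <- apply(f@positions, 1, function(r)
      paste(.fmt_num(r), collapse = " "))
    if (hasV) {
      vls <- apply(x@velocities[[k]], 1, function(r)
        paste(.fmt_num(r), collapse = " "))
      writeLines(paste(f@species, poss, vls), con)
    } else writeLines(paste(f@species, poss), con)
  }
  invisible(path)
}

#' Write an APT dataset to the plain-text container format
#'
#' The container stores, per record: the configuration id, the cell and
#' periodicity flags, the split label and one line per atom holding the
#' element symbol, the position and the 9 tensor components, all at full
#' double precision (lossless round trip).
#'
#' @param dataset an \linkS4class{APTDataset}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAPTDataset <- function(dataset, path) {
  validObject(dataset)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# aptIR APT dataset v1",
               sprintf("nrecords %d", nRecords(dataset))), con)
  for (k in seq_len(nRecords(dataset))) {
    r <- dataset@records[[k]]
    cfg <- r$config; n <- nAtoms(cfg)
    writeLines(c(sprintf("record %s", if (nzchar(cfg@id)) cfg@id else
                           sprintf("rec%06d", k)),
                 sprintf("natoms %d", n),
                 if (is.null(cfg@cell)) "cell none" else
                   paste("cell", paste(.fmt_num(t(cfg@cell)), collapse = " ")),
                 paste("pbc", paste(ifelse(cfg@pbc, "T", "F"), collapse = " ")),
                 sprintf("split %s", dataset@split[k])), con)
    tn <- r$apts@tensors
    rows <- vapply(seq_len(n), function(a)
      paste(cfg@species[a],
            paste(.fmt_num(cfg@positions[a, ]), collapse = " "),
            paste(.fmt_num(as.vector(t(tn[, , a]))), collapse = " ")),
      character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read an APT dataset written by \code{\link{writeAPTDataset}}
#' @param path file path.
#' @return an \linkS4class{APTDataset}.
#' @export
readAPTDataset <- function(path) {
  lines <- readLines(path)
  .stop_if(length(lines) < 2L || !startsWith(lines[1], "# aptIR APT dataset"),
           "not an aptIR APT container: ", path)
  nrec <- as.integer(strsplit(lines[2], "\\s+")[[1]][2])
  i <- 3L
  configs <- vector("list", nrec); apts <- vector("list", nrec)
  split <- character(nrec)
  for (k in seq_len(nrec)) {
    id <- sub("^record\\s+", "", lines[i])
    n <- as.integer(strsplit(lines[i + 1L], "\\s+")[[1]][2])
    cellTok <- strsplit(lines[i + 2L], "\\s+")[[1]]
    cell <- if (cellTok[2] == "none") NULL else
      matrix(as.numeric(cellTok[-1]), 3, 3, byrow = TRUE)
    pbc <- strsplit(lines[i + 3L], "\\s+")[[1]][-1] == "T"
    split[k] <- strsplit(lines[i + 4L], "\\s+")[[1]][2]
    body <- lines[(i + 5L):(i + 4L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    tokm <- do.call(rbind, toks)
    sp <- tokm[, 1]
    pos <- matrix(as.numeric(tokm[, 2:4]), n, 3)
    tnum <- matrix(as.numeric(tokm[, 5:13]), n, 9)
    tens <- array(0, c(3, 3, n))
    for (a in seq_len(n)) tens[, , a] <- matrix(tnum[a, ], 3, 3, byrow = TRUE)
    configs[[k]] <- atomicConfiguration(sp, pos, cell = cell, pbc = pbc,
                                        id = id)
    apts[[k]] <- aptFrame(tens, configId = id)
    i <- i + 5L + n
  }
  aptDataset(configs, apts, split = split)
}

#' Split an APT dataset by configuration
#'
#' Assigns train / holdout labels at the configuration level: every atom of a
#' configuration shares its configuration's split (splitting by atom would
#' leak near-duplicate environments between splits). Deterministic for a
#' given seed.
#'
#' @param dataset an \linkS4class{APTDataset}.
#' @param trainFraction fraction of configurations assigned to training
#'   (0 < f < 1). With 10 configurations and 0.9 this reproduces the canonical
#'   3456 / 384 tensor split for 384-atom configurations.
#' @param seed integer seed.
#' @param holdout label for the held-out configurations ("validation" or
#'   "test").
#' @return the dataset with split labels assigned.
#' @export
splitDataset <- function(dataset, trainFraction = 0.9, seed = 1L,
                         holdout = c("validation", "test")) {
  holdout <- match.arg(holdout)
  n <- nRecords(dataset)
  .stop_if(n < 2L, "cannot split fewer than 2 configurations")
  .stop_if(trainFraction <= 0 || trainFraction >= 1,
           "trainFraction must lie strictly between 0 and 1")
  nTrain <- max(1L, min(n - 1L, round(trainFraction * n)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(seed, "split"))
  ord <- sample.int(n)
  split <- rep(holdout, n)
  split[ord[seq_len(nTrain)]] <- "train"
  new("APTDataset", records = dataset@records, split = split)
}

# save/restore the global RNG state so package internals do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
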