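BASES6 <- c("A", "T", "C", "G", "N", "del")

#' Read pooled allele counts in sync format
#'
#' Parses the popoolation2-style sync interchange format: tab-separated
#' `contig  pos  ref  A:T:C:G:N:del [A:T:C:G:N:del ...]` with one
#' colon-separated count column per pool and 1-based positions. Counts are
#' strandless; strand is ignored throughout.
#'
#' Validation is strict: a record with the wrong number of pool columns, a
#' count field without exactly six entries, or a negative / non-integer
#' count raises an error naming the offending line. An empty file yields an
#' empty object with a warning.
#'
#' @param path path to a sync file.
#' @param pool_sizes integer vector of haploid pool sizes, one per pool.
#'   Pool sizes are always supplied by the caller (they cannot be inferred
#'   from read counts).
#' @return an object of class `sync_counts`: a list with `sites` (data.frame
#'   `contig`, `pos`, `ref_base`), `counts` (list of `n_sites x 6` integer
#'   matrices, one per pool, columns A,T,C,G,N,del) and `pool_sizes`.
#' @export
read_sync <- function(path, pool_sizes) {
  if (!file.exists(path)) stop("sync file does not exist: ", path)
  pool_sizes <- as.integer(pool_sizes)
  stopifnot(length(pool_sizes) >= 1L, all(pool_sizes >= 2L))
  if (file.size(path) == 0L) {
    warning("empty sync file: ", path)
    return(empty_sync(pool_sizes))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", showProgress = FALSE)
  n_pools <- length(pool_sizes)
  if (ncol(dt) != 3L + n_pools) {
    stop(sprintf("sync file %s has %d columns; expected %d (3 + %d pools)",
                 path, ncol(dt), 3L + n_pools, n_pools))
  }
  pos <- suppressWarnings(as.integer(dt[[2L]]))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) {
    stop("sync line ", bad[1L], ": position must be an integer >= 1, got '",
         dt[[2L]][bad[1L]], "'")
  }
  counts <- vector("list", n_pools)
  for (j in seq_len(n_pools)) {
    fields <- data.table::tstrsplit(dt[[3L + j]], ":", fixed = TRUE)
    if (length(fields) != 6L) {
      # find the first offending line for the error message
      nf <- lengths(strsplit(dt[[3L + j]], ":", fixed = TRUE))
      bad <- which(nf != 6L)[1L]
      stop(sprintf("sync line %d, pool %d: count field '%s' does not have 6 entries",
                   bad, j, dt[[3L + j]][bad]))
    }
    m <- matrix(0L, nrow(dt), 6L, dimnames = list(NULL, BASES6))
    for (k in 1:6) {
      v <- suppressWarnings(as.numeric(fields[[k]]))
      bad <- which(is.na(v) | v < 0 | v != floor(v))
      if (length(bad)) {
        stop(sprintf("sync line %d, pool %d: count '%s' is not a non-negative integer",
                     bad[1L], j, fields[[k]][bad[1L]]))
      }
      m[, k] <- as.integer(v)
    }
    counts[[j]] <- m
  }
  sync <- list(sites = data.frame(contig = dt[[1L]], pos = pos,
                                  ref_base = dt[[3L]],
                                  stringsAsFactors = FALSE),
               counts = counts, pool_sizes = pool_sizes)
  class(sync) <- "sync_counts"
  sync
}

empty_sync <- function(pool_sizes) {
  n_pools <- length(pool_sizes)
  sync <- list(sites = data.frame(contig = character(), pos = integer(),
                                  ref_base = character(),
                                  stringsAsFactors = FALSE),
               counts = replicate(n_pools,
                                  matrix(0L, 0L, 6L,
                                         dimnames = list(NULL, BASES6)),
                                  simplify = FALSE),
               pool_sizes = as.integer(pool_sizes))
  class(sync) <- "sync_counts"
  sync
}

#' Write pooled allele counts in sync format
#'
#' Inverse of [read_sync()]; `read_sync(write_sync(x, f), pool_sizes)`
#' reproduces `x` exactly.
#'
#' @param sync a `sync_counts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path) {
  stopifnot(inherits(sync, "sync_counts"))
  cols <- lapply(sync$counts, function(m) {
    do.call(paste, c(as.list(as.data.frame(m)), sep = ":"))
  })
  dt <- data.table::as.data.table(
    c(list(sync$sites$contig, sync$sites$pos, sync$sites$ref_base), cols))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.sync_counts <- function(x, ...) {
  cat(sprintf("<sync_counts> %d sites, %d pools (haploid sizes: %s)\n",
              nrow(x$sites), length(x$counts),
              paste(x$pool_sizes, collapse = ", ")))
  invisible(x)
}
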