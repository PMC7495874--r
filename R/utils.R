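# internal helpers

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Write `lines`/callback output atomically: temp file in the same
# directory, then rename. No partial artifact survives a failure.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("failed to move temporary file onto ", path)
  invisible(path)
}

# FNV-1a 32-bit hash of a string, returned as 8 hex digits. Used only to
# stamp outputs with a config fingerprint; not cryptographic.
fnv1a_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # xor only touches the low byte (b < 256); avoids 32-bit bitwXor limits
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(lo8, b)
    # 32-bit modular multiply by the FNV prime 16777619
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  # h is a double holding a 32-bit value; format halves as hex
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
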