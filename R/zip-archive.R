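# Minimal deterministic ZIP writer.
#
# The final focus folders are packaged as a standard ZIP archive.  Entries
# are deflate-compressed by reusing the raw deflate stream inside R's zlib
# output (memCompress), with CRC-32 computed by the usual table-driven
# reflected polynomial.  Timestamps are pinned to the DOS epoch so archives
# from repeated runs are byte-identical.

.CRC_TABLE <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320 as signed int
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   .CRC_TABLE[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.double(crc)
}

# little-endian unsigned integer as n raw bytes
le_bytes <- function(x, n) {
  as.raw((x %/% 256^(0:(n - 1))) %% 256)
}

# raw deflate stream for a raw vector: strip the 2-byte zlib header and
# 4-byte Adler-32 trailer from memCompress output
deflate_raw <- function(bytes) {
  z <- memCompress(bytes, "gzip")
  z[3:(length(z) - 4)]
}

#' Write a ZIP archive
#'
#' Deterministic ZIP writer used to package final pipeline output: fixed
#' (epoch) timestamps, deflate compression, forward-slash entry names.
#'
#' @param zipfile Output archive path.
#' @param files Character vector of file paths, relative to `root`.
#' @param root Directory the entry names are resolved against.
#' @return `zipfile`, invisibly.
#' @export
write_zip <- function(zipfile, files, root = ".") {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  centrals <- vector("list", length(files))
  offset <- 0
  dos_time <- as.raw(c(0x00, 0x00))  # 00:00:00
  dos_date <- as.raw(c(0x21, 0x00))  # 1980-01-01
  for (k in seq_along(files)) {
    path <- file.path(root, files[k])
    data <- readBin(path, "raw", n = file.info(path)$size)
    comp <- deflate_raw(data)
    crc <- crc32(data)
    name <- charToRaw(gsub("\\\\", "/", files[k]))
    header <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)), le_bytes(20, 2), le_bytes(0, 2),
      le_bytes(8, 2), dos_time, dos_date, le_bytes(crc, 4),
      le_bytes(length(comp), 4), le_bytes(length(data), 4),
      le_bytes(length(name), 2), le_bytes(0, 2), name
    )
    offsets[k] <- offset
    writeBin(header, con)
    writeBin(comp, con)
    offset <- offset + length(header) + length(comp)
    centrals[[k]] <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)), le_bytes(20, 2), le_bytes(20, 2),
      le_bytes(0, 2), le_bytes(8, 2), dos_time, dos_date, le_bytes(crc, 4),
      le_bytes(length(comp), 4), le_bytes(length(data), 4),
      le_bytes(length(name), 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4), le_bytes(offsets[k], 4),
      name
    )
  }
  cd_start <- offset
  for (entry in centrals) {
    writeBin(entry, con)
    offset <- offset + length(entry)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)), le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(length(files), 2), le_bytes(length(files), 2),
    le_bytes(offset - cd_start, 4), le_bytes(cd_start, 4), le_bytes(0, 2)
  )
  writeBin(eocd, con)
  invisible(zipfile)
}
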