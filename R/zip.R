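# Minimal ZIP writer (STORE method, no compression). The dissemination
# bundles are small text/PNG files, so stored entries are adequate and keep
# the archive readable by any unzip implementation (including R's internal
# one).

.zip_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.zip_u32 <- function(x) {
  x <- as.numeric(x)
  b <- raw(4)
  for (i in 1:4) { b[i] <- as.raw(x %% 256); x <- x %/% 256 }
  b
}

# files: named character vector, names = archive entry names, values = paths
.write_zip <- function(files, zipfile) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  sizes <- numeric(length(files))
  crcs <- numeric(length(files))
  pos <- 0
  dostime <- .zip_u16(0L)
  dosdate <- .zip_u16(0x21L)  # 1980-01-01
  for (i in seq_along(files)) {
    data <- readBin(files[[i]], "raw", n = file.size(files[[i]]))
    nm <- charToRaw(names(files)[i])
    crcs[i] <- cpp_crc32(data)
    sizes[i] <- length(data)
    offsets[i] <- pos
    hdr <- c(.zip_u32(0x04034b50), .zip_u16(20L), .zip_u16(0L), .zip_u16(0L),
             dostime, dosdate, .zip_u32(crcs[i]), .zip_u32(sizes[i]),
             .zip_u32(sizes[i]), .zip_u16(length(nm)), .zip_u16(0L), nm)
    writeBin(hdr, con)
    writeBin(data, con)
    pos <- pos + length(hdr) + length(data)
  }
  cdstart <- pos
  for (i in seq_along(files)) {
    nm <- charToRaw(names(files)[i])
    cd <- c(.zip_u32(0x02014b50), .zip_u16(20L), .zip_u16(20L), .zip_u16(0L),
            .zip_u16(0L), dostime, dosdate, .zip_u32(crcs[i]),
            .zip_u32(sizes[i]), .zip_u32(sizes[i]), .zip_u16(length(nm)),
            .zip_u16(0L), .zip_u16(0L), .zip_u16(0L), .zip_u16(0L),
            .zip_u32(0L), .zip_u32(offsets[i]), nm)
    writeBin(cd, con)
    pos <- pos + length(cd)
  }
  eocd <- c(.zip_u32(0x06054b50), .zip_u16(0L), .zip_u16(0L),
            .zip_u16(length(files)), .zip_u16(length(files)),
            .zip_u32(pos - cdstart), .zip_u32(cdstart), .zip_u16(0L))
  writeBin(eocd, con)
  invisible(zipfile)
}
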