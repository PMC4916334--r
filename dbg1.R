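library(walkcounts)
# 1. sinusoid counts error by frequency
for (f in c(0.9,1,2,3,5)) {
  n<-300; t<-(0:299)/60
  rec <- triax_recording(rep(0,n),rep(0,n),1+0.5*sin(2*pi*f*t),fs=60)
  cnt <- epoch_counts(segment_epochs(rec)[[1]])
  cat(f, "relerr:", (cnt$counts-0.5*2/pi*5)/(0.5*2/pi*5), "\n")
}
# 2. jsonlite digits
x <- c(0.3794161658247299784, pi/7)
tmp <- tempfile()
jsonlite::write_json(list(v=x), tmp, digits=NA)
cat(readLines(tmp), "\n")
y <- jsonlite::read_json(tmp, simplifyVector=TRUE)$v
cat("identical:", identical(x,y), "\n")
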