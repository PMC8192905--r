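# Pin BLAS to one thread: reproducible timings and no oversubscription on
# single-core machines.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")
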