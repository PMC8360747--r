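#include <Rcpp.h>
#ifndef _WIN32
#include <dlfcn.h>
#endif

// Pin the BLAS thread pool at runtime. On a single-CPU host OpenBLAS
// oversubscribes its default pool and gemm throughput collapses; one thread
// is also what makes repeated training runs bit-reproducible.
// [[Rcpp::export(name = ".set_blas_threads_cpp")]]
bool set_blas_threads_cpp(int n) {
#ifndef _WIN32
  typedef void (*setter_t)(int);
  void* sym = dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (sym == nullptr) return false;
  reinterpret_cast<setter_t>(sym)(n);
  return true;
#else
  return false;
#endif
}
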