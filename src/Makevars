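# The conda cross toolchain in this image targets a newer glibc sysroot
# than the system runtime, so objects it builds fail to load
# (GLIBC_2.38 symbol versions).  Build with the system toolchain instead.
# src/Makevars is read before Makeconf, hence the override directives.
override CXX17 = /usr/bin/g++
override CXX = /usr/bin/g++
override CC = /usr/bin/gcc
override SHLIB_CXXLD = /usr/bin/g++
override CXXFLAGS = -O2 -fPIC
override CXX17FLAGS = -O2 -fPIC
override LDFLAGS = -L/opt/conda/envs/bio/lib
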