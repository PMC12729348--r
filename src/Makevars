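# The direct convolution kernel relies on auto-vectorization; compile it
# with AVX2/FMA codegen (x86-64-v3, any 2013+ x86_64 CPU) and -O3.
KERNEL_FLAGS = -O3 -march=x86-64-v3 -funroll-loops -ffast-math

all: $(SHLIB)

conv_ops.o: conv_ops.cpp
	$(CXX) $(ALL_CPPFLAGS) $(ALL_CXXFLAGS) $(KERNEL_FLAGS) -c conv_ops.cpp -o conv_ops.o
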