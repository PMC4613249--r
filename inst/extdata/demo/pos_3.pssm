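
Last position-specific scoring matrix computed
             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 V   1  -4  -4   3   1  -2   1  -1   4   3   6  -2   3   4   3   2  -3   0  -1   5
    2 C   4   2   2   4  -1  -1  -3   3  -2  -2  -3  -2   2  -2  -3   3  -4   4  -4   2
    3 M   3   0  -4   1   1   1   2   4   0  -2  -4  -2   1   2  -3  -4  -3  -4  -1   1
    4 T  -4   0   4  -2  -2   1   0   3   2   1  -3   3  -3  -1   4   3   6   0   3   4
    5 A  -2  -2  -3   3  -1   3  -1  -2   4   2   2   1  -2   1  -1  -1  -2  -4   4   0
    6 N   3  -2   5   1   0   5  -1  -2   3  -2   4  -1  -4   1   4  -3  -3   3   0   0
    7 D   3   2   4  -2   3  -1   5   1   4   1  -4   0   4  -1   0  -3  -2   0  -1  -4
    8 S   0   2  -3   1   2  -3   0   4  -2  -3  -1   1   4  -4   3   3  -1  -4  -2   2
    9 I   0   4   4   2  -4   2   1  -2  -2  -1  -2   2  -2   3   0   3  -4  -4   4  -1
   10 T   1   4   0   4   1  -2   4  -3   2   3   0   3  -4  -4   1   2   2   2   3  -2
   11 G   2  -1   0   2   4  -1  -3   0  -2  -1  -1  -3  -2   4   6   0  -3   3  -4  -1
   12 S   0  -1  -3   0   1   1  -4   2   2  -1  -2   3  -1   3   4   0   6  -4  -3   1
   13 L  -2  -2  -2   1  -1   2  -3  -1  -1   3   4  -4   1   4   4  -4  -3  -4   3   1
   14 I   2  -3   2  -2   3  -1   0   3   4   3   2  -1  -1   2   0   1   2  -1   1   4
   15 D   3   2  -2   6  -4   2   0  -1   4   0  -3  -2   4   2   0   0   4  -1   3  -1
   16 F  -4  -2   1   1   3  -4  -2  -1   3  -1   2   0  -1   0   0  -3  -2   5  -1   0
   17 V   1   1  -1   1  -4   1  -3   4  -2  -2   6   4   1  -3  -1  -2   4   4  -2   3
   18 S  -1   0   0   3   2  -1   2   1   3  -2   2   4  -4  -3   2   4   1   0   4   1
   19 S  -4  -3  -1  -2   0   1   1  -4  -3   1  -1   0  -2  -4   3   6   1   3  -2  -2
   20 V   6   2   4   3   3  -3   3   5  -1  -1   0  -4  -3  -4   5   3  -1   3   3   0
   21 I   1  -4   2  -4   1   3   4   6   2   4  -1  -3  -2  -3   4   0   3   3  -4  -1
   22 P   0   3  -2   4   0   1   4   6   1   2  -2   1  -4   0  -1   4  -3  -3  -1   6
   23 G   0  -2  -3   2  -4   1   1  -1  -3   0  -2  -4   4  -2   6   2  -1  -3  -1   2
   24 S   1  -4  -3  -1   4   1   4   4  -4  -2   3  -1  -4   2   1   2   0   2  -4  -1
   25 S  -3  -1   3   1   2   0   4   3   4   3   3  -2  -4  -3   4   5   4   1   1  -3
   26 L   6  -1  -1   4  -2  -4   4   2  -1  -1   3   1  -2   1   2   1   4   4  -1   1
   27 H   3   2  -1  -3   0  -3  -3  -2   0   0  -1  -3  -4   1   4  -3  -3  -4   2  -1
   28 Q  -2  -4   0   0   4   4  -3   3   3  -3   0   0  -4   0   2   0  -4   0   2   4
   29 T  -4   2  -2   2   4  -3   4   0  -2   2   2   4  -2  -4   2   3   2  -3   1   2
   30 V   0   1   0  -1  -1   1   3   1  -2  -1   3  -1   1   3   1  -2   0  -3   0  -2
   31 P   2  -4  -1  -2  -3  -3  -4   4  -2   1   4   3  -3   3   1  -1  -1   4   3   0
   32 F   0  -4  -2  -2   1  -3  -1   1  -2  -2  -3   0  -1   0  -1  -2  -2   1   6   3
   33 A   1  -1  -1   4   3   4  -1   3  -4   1   1   4  -3  -1   3   3  -1   0  -2   6
   34 N  -1  -3   4  -2  -3   2  -2  -4  -1   2  -1  -1   2   1   1  -2   2  -3   4   0
   35 L   0   4   0   3  -3   4   3   4   4   5   4  -4  -2   3  -2   4   0  -2  -3   0
   36 Q   2   2  -1   0   0   5   1   2  -3   1  -2  -3   0  -2  -1   3  -3   3   3   2
   37 Q   4  -3   5  -4   2  -2  -2  -3   2  -2   4   0   3   3   0   2  -4  -2  -4  -2
   38 V   0   3   4  -3  -3  -3   3   0  -4   5   6   0   0   2  -2   4  -2   2  -4  -2
   39 R  -2  -1   3   0  -3  -1  -4  -4  -1   4   1   4   4   3   1   4  -3  -2   2   2
   40 T   1   4   0  -1   2   1   4   0  -1   1  -1  -4  -2  -2   1   0   6   1  -1   0
   41 I   5   1  -2  -3   4   2  -1   0  -4   0   6   3  -4   1   4  -2  -1   2  -3   6
   42 V   4   0   0   1   4  -2  -2   5   1   2   2   0  -1   0   1  -2  -3   1   3   2
   43 T   0   1   2  -2  -4  -4  -2   1  -2   1  -3  -3   3   0  -2   6   1  -4   2  -3
   44 S   2   3  -4   4   3   3   2   0  -1   2  -1   4   1  -2   3  -1  -2  -2   3   4
   45 A   0   4  -4   4  -1   4   4   0   0   3   5  -4  -1   4   0   0   0   3  -4   6
   46 T   0  -1  -3   2  -4  -3   0   3   2  -3  -4  -2   0  -4   2   1   6   0  -4   0
   47 S  -4   4   1   3  -4   4  -1  -2   4   0   0  -3  -2   0  -2   5   0  -1   4   3
   48 I  -2   0  -1   4   4  -1  -4   0  -3   2   1  -1  -2   4  -2   1  -4  -1   0   3
   49 M  -3   4   3   2  -1  -3  -3   4   3  -2   0   4   2   3   2   0   1  -3  -4   4
   50 T  -1  -4  -4  -2   1   2   3  -4  -4   2  -2  -2  -3   2  -4   6  -2   1  -2   2
   51 I   6   4   0   4  -3   3   1  -2   2   3   5   0  -3   4   3  -1   3  -2   3   1
   52 I   3  -2  -3   0  -3   0   2   3   3   6  -2   3  -4   1   3  -3  -1   3   0   0
   53 S  -4   0   2   0   1  -4  -1   1  -4   2  -1  -3   3   1  -3  -2   1  -1  -1   3
   54 P   0  -4   1  -2   1  -3  -2   6   3   3   3  -2  -3   1   5   1  -4   3  -2  -1
   55 L   1   0   1   1   0  -4  -4   4   0   5   5   0  -1  -1  -2  -2   3   2   2   5
   56 Q  -3  -2   3   0  -4   4  -2  -2   1   0   4  -2  -2   1  -2   2   3  -3   2  -4
   57 H  -4  -4   4   1   4   0  -3  -4  -2   4   3   4   1   3   3   4   4   1   1   3
   58 G   4   3   1  -1  -3  -2   4   4   2  -1  -1  -2   0  -2   0   3   0   0   1   0
   59 V   2  -4   4  -2  -1  -1  -3   0  -1   6  -2  -4   3  -1   1   3   2   0  -1   6
   60 I  -2   4  -1  -3   4   3  -2   4   4   4   4  -3  -3  -1   3  -2  -4   0  -1   6
   61 Q   3  -3   3  -3   3   2   2  -2  -3   2   3   1   1  -3  -3  -2  -4   0   2  -1
   62 P  -2  -4  -2  -2  -1   2  -3  -1   1  -2   4   1   4  -1   5   3  -3   4  -3   5
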