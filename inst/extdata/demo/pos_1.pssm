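
Last position-specific scoring matrix computed
             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 T  -4  -3  -2  -3  -2   4   4  -3   2   2   2  -1   4   4  -1   0   4   4   4   2
    2 C   3   0   3  -1  -2   1  -2   2   0   0  -4  -1   4   1  -3   0  -1  -1   4   4
    3 D   1   3  -3   1   4   1   1  -1   1   1  -3   3   3   3  -3  -2   0   4  -1   0
    4 G   3  -3   3   1   2   2   3   0   2  -1  -1   1  -2   0  -2   2  -3   0   3  -2
    5 A   5   2   2   3  -4  -3  -4   3   3   4   4   3  -4  -1  -1  -3   1  -4  -4   5
    6 V  -1   3   4  -4  -2  -1  -3   5   3  -2   5   0  -2   3   1   4  -4  -4  -4   6
    7 M   4  -1   0  -1   1   1  -4   2   2   4  -4  -4   5   4  -1  -4  -4  -3   0   2
    8 T   1   2  -1   3   0   2   4  -1   4  -2   1   1  -2   2  -4  -1   2  -3   4   4
    9 K  -2   0   3  -2  -3  -1  -2   4   2   3  -4   1  -1   4  -3   4  -4   2   4  -4
   10 T  -4   2  -2   0   3   0  -2   4  -3   3  -4   1  -1   3  -2   4   3  -1   3  -1
   11 N   1  -2   0  -2  -4  -1  -1   0   4   0   1   4  -2   4  -4  -2   1   3   2  -4
   12 S   4   3  -4   0   1   0   0   4  -3   2   1   0  -2   0  -2   5   4  -2   3   2
   13 T  -4   2   1  -3  -4   3   2  -2   3  -3   1  -2   4   2   3  -1  -2  -3   1   4
   14 G   6   3   3  -2   1  -3   4   6   0   2   6  -4   1  -4  -2   0   4  -3   3   0
   15 K  -3  -4   4   3   4  -2  -3  -4   2  -1  -3   6   3  -2  -4  -2  -3  -2   2   4
   16 I   5   3  -2   2   3  -2   3   2  -3   0   4  -3   4   4  -2   2   1   3  -2   3
   17 N   3  -3   3  -4   3   3   2   3   3  -2  -2   2   2  -2   3  -4  -4   4  -4  -3
   18 P   3  -4   0  -2   1   0  -2   0  -2   6   5   3  -3  -3   2   4  -1  -4  -1   1
   19 I   0  -2  -2   0   2  -2   2   5   2   2   3   2   4   1   0   2  -3   1  -3   3
   20 S  -1  -1   1  -3  -1  -4   1  -2   3   2   4   4  -1   3  -4  -2   6   0   3  -1
   21 S  -2  -3  -2  -3  -2   2   2   4   0  -2   3  -2  -4   1   2   5   3  -4  -4  -3
   22 V   3   0  -2  -1  -1  -3   0  -2   1   4   5  -1   2  -2   1  -3  -4  -2  -1   3
   23 N  -2  -3   2   0   0   4   1   0  -2  -3  -1   3   3  -3  -3  -4   2  -1  -3  -3
   24 T   2  -4   2  -3  -1  -1   3   1  -1   0   1   2   0  -1   3   6   4   3  -2  -3
   25 W   4  -2   2  -3  -1  -3  -1   1  -2   4  -3   1  -1  -1  -1   1   4   2   2  -2
   26 P  -1  -4   0  -2  -2  -1   2  -1  -3   4  -1  -2   0  -4   1   0  -2   0  -3   6
   27 G   6  -3  -4   4   3   2  -1   0  -1   5   5  -2  -3  -3   2  -3  -4   4   2  -2
   28 S   2  -1  -1   3  -4  -2  -2   1  -4   3  -1  -4   2   2   0  -1  -2  -3   3  -4
   29 Y  -1  -2   2   0   4  -1  -1   2   1  -2  -3   0  -1   4  -4  -3   3  -2   2   2
   30 S   1   1  -2   3   3   1   0   4   3  -3   4   0   1   2   4   3   3   0   1   3
   31 P   3   1  -3  -3   4   1   1   5   2   3  -2  -3   2   2   0   1  -4  -1  -4   4
   32 H   1  -2   2   0   4   4  -3  -1  -2  -1  -1   2  -3  -4   0   2   1   0  -2   1
   33 C  -2   0  -2  -4   2   2  -4  -4  -3   4  -3  -1  -2   3   0   2   1   1   4   3
   34 P  -1  -1   0  -2   3  -4  -4  -1   4   3   3   0  -3   3  -2   3   4   4  -4   5
   35 Q  -1  -3   3   3   0   2  -1  -4  -3   4  -2   4  -2  -2   1   1  -1   3   2  -4
   36 K   4   0   1   1  -4  -1  -2  -3   0  -3   1   3  -1   3   0   1  -4   4   3  -4
   37 V   0   2   0   3   1   3  -3   3   1   4   2   2   1   3   1   2  -4  -3   2   2
   38 V   0   0   4  -2   0   1   1   1   0  -2   3  -2   2  -3   5  -4   2  -3   1   3
   39 N  -1  -1   5   2  -1  -2  -3   0   1   3   3   0  -2   3  -1  -1   0  -1   1  -2
   40 P   4   1  -4   2   2   2   2   3   2   2   3   4  -1   0  -1  -4  -2  -1   1   6
   41 P   5  -4   3   2  -4  -1   3   3   2   6  -1  -1   0   0   0  -2   2   0  -3   4
   42 S  -3   0   0  -4  -3  -4   4   1  -3   3  -1  -2   4   4   2   2   4   1   0  -1
   43 G   3  -1  -4  -3  -3   4  -3   5   0   5   0   2   0   4   2  -3   0  -3   4   0
   44 V   6   2   3   2   4  -4  -4   4  -3   1   3   4   3   0   3   0  -2   3  -2   5
   45 A  -1  -2   0   3  -4  -1   1  -1   2   4   4  -4  -1   0  -2  -1  -3  -2  -3   0
   46 I   3  -3   4   4  -2  -1  -4   1  -3   2   1   4   4  -1   1  -1  -2   4   1   2
   47 G   3  -3  -3   1  -2   4   4   2   4   6  -2   0   2   2  -2  -2  -4   2   3   0
   48 S   1  -1  -3  -1   2   0   3  -2  -3   2   3  -2  -1   3   0  -1   2   0   4   2
   49 T  -4   1   3   4  -2  -4  -2  -4  -4   2  -1   3   3  -1   1   2   0  -1  -2  -1
   50 V   2   1  -4   3   2   4   0   0  -4   4   1  -3  -3   1   4   4  -4   1  -1   1
   51 N   0   4  -2   1   4   1  -3   0  -2   0   3  -4   1   4   2   0   0   1   2  -2
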