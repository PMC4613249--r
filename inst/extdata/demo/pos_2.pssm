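
Last position-specific scoring matrix computed
             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 S   1  -1   0   4  -4   1  -3  -1   4  -4  -1  -2  -4  -2  -4   5   5   2   4   1
    2 V   1  -4  -3  -1   2  -2  -1   3   4   3  -2   3  -4  -4   3   2   2   4   4   1
    3 Q   0  -1  -2   4   3   3   0  -3   0   1   0   1   3  -3   0  -1   3   1   1  -2
    4 P   1   0  -2  -1   1  -1   0   3   3   2   5  -1   3  -2  -2   0  -4  -2   2   3
    5 N  -3   2  -1   4   3   5   4  -3   2  -4   3  -3  -1  -1  -2  -4  -2   4   2   3
    6 I   4  -2  -3  -2  -2  -3   2   5   3   2   2   0  -2   4   3   1   1  -4   4  -1
    7 E   2   1   4  -2   3   1  -1   4  -1  -4   3  -2   3  -4  -3   2   3   3  -3  -3
    8 G   6   1   2   1  -4  -4  -2   5  -2   4   5   3  -4   2   0  -3  -2  -3   3   6
    9 N   2   3   6  -4   0  -2  -3   0  -3  -3   0   1  -3  -2   4   4   4   2   2   4
   10 N  -1   3  -2   0   4   2   2   0   3   3   4   4   0  -1  -4   2  -4  -4  -1  -1
   11 P   2   1  -4   0   2   4  -2   1  -4   4   2   4  -3   2  -2   2   3  -4  -4   4
   12 T   0   1  -2  -1  -1  -2  -1   0   1  -4   2   0   1  -1   4   3  -2  -3  -2   4
   13 P   6   4  -3   1  -3  -3   0   4  -4  -1   0  -4   1   4  -1   2  -4   0  -4  -1
   14 V   5   3   2  -3  -1   4  -2   6  -2   1   6   1  -3  -2   3  -2  -3   1   4   6
   15 Q  -4  -3   3   2   4   0   1   1  -3  -1   0   2   0  -1  -1  -4   2  -1   3   0
   16 G   3  -3  -2   0  -1  -2  -4   4   0   5   1   1  -2   1   3  -4  -3   3  -4   2
   17 N   2   0  -2   4  -3   2   3  -1  -4  -4   1   4   3   2   4   4   1   4   4  -1
   18 S   2   3   1   3   4   4   0   1  -2  -1   3  -4  -4  -1   3   5   1  -3   3   4
   19 P   1   1  -2   0   1   2   2   3   0  -2   4  -3   0   1  -1  -1   4   3   0   0
   20 N   4   0   0  -4   1   6   1  -4  -4   0   2  -4   3   0   1  -4   4   2   1   4
   21 T  -3   2   2   2   4   0   4  -4   1  -2   4  -4   4   4   4  -1   0   3  -2   2
   22 N   1   4   6   2  -1  -2  -2  -3  -4   1   1   4   2   0   1  -4   3   3  -4   0
   23 A   4   2   4  -3  -3  -3  -4   3  -1   3   6   2  -2   1   4  -4  -1  -4  -3  -2
   24 S  -3   2   2   4   3   0   0   4   1   3  -3   1   4  -2   1   4   5  -4  -1  -1
   25 G   2  -4   0  -3  -2  -2  -2   1   1   0  -2  -3   4  -4   6  -4   2  -1  -2   1
   26 A   1  -1   4   0   3   3  -1   1   2   1   1  -3   3   1  -1   4   2   3   4  -1
   27 W   3   1   4   2  -2  -4  -4  -4   3  -3  -4  -3   2   2   4  -2   1   2   4   3
   28 N   3   1  -2  -1   3   3   1  -4   1  -3  -1  -2  -3   3   4  -4  -1  -2  -2   4
   29 T   2   0   3   4  -3   1   2   1  -1   4  -1  -1   1  -1   0   0   4   3   0  -4
   30 K  -3  -1   1   2   2  -4  -2  -3   1   4   3   4  -4   0   3   2   3   0  -1  -4
   31 L  -1  -2   2  -2  -1   3   2  -2   4   5  -1  -4   3   1   3  -1   0   0   1   5
   32 C  -2   0   2   1   5  -3   0   3   0  -3  -1  -3   1  -3   3  -3  -3   3  -4   0
   33 P   6  -1   1   1  -4   0   4   3  -2   5   0  -2  -1  -3   3  -1   4   1  -2   6
   34 S  -1  -2   4  -1   4   3  -4   4   3   2  -1  -1  -3   0  -1   1  -2  -1  -3  -3
   35 G   4   0   4  -4  -3  -4   2   2   0   1   3   0  -3   3   1   2  -2  -2   1  -1
   36 T   3   3  -1   2   3   2  -4  -4   4  -4   1  -4  -3   2   1   3   1   3  -4   3
   37 G   3   1  -1   1   2   3   0   6   4  -2  -2  -2  -4  -4   2   2  -4   2  -1   2
   38 A   6   1   2   4  -4   0  -1   1  -3   6  -2   4   1   2   5  -1   1  -2  -1  -2
   39 W  -1  -4  -2  -4   0  -2   0   3  -2   3  -3  -2   0  -2  -1  -3  -3   5   1   4
   40 L   3   0  -4  -2  -4  -3   2   1  -1   0   1  -3   0  -2   0   4   1  -4  -4   4
   41 N  -4  -4  -2  -3   2   3   4   2  -3  -3   2  -2   0  -4  -1  -4  -1   2  -4   3
   42 P   5  -3   4   4   0   1  -4  -2   4   5   4  -2   1  -4   1   1  -2  -4   0   2
   43 N   1   0   1   4   1   4   2   0   4   1  -2  -2   3   3  -4   2   0  -3   1  -3
   44 A   2   3   2  -3  -2  -4   1   6   0   1  -2  -2  -2  -4   4  -1  -3  -4  -1   3
   45 N   3  -1   1  -3  -2   0   2   3   0   1   1  -2   0  -3  -4   4   2  -4  -1   2
   46 M   4  -2   3   0   3  -1   2  -1   1   1   0   3   5  -1  -2   3  -2  -4   0  -3
   47 T  -1  -1   3   1   3   2  -2   0   4   0  -1   0   0   0   3   3   3   4   0   2
   48 S  -3  -4  -1   0  -2  -3   0   4   0   4   3   4   1  -3   0   3   0   2  -3   4
   49 N  -4   4   2   3   4   6   1  -3   4   2  -1   4   1   0  -1  -2  -2  -1   1   4
   50 I   3  -4   2   4  -2   1  -2   1   0   3  -2   3   1   2   2   0   0   1   3   0
   51 S   1   3  -1  -3  -2   0   1  -4   3  -2   1  -2  -2   0  -4   1   1   1  -1   0
   52 P   3  -1   1  -3   2  -3  -2  -2  -4   6   6   4   1  -1  -2  -4  -2  -1  -3   4
   53 I   6  -2   3  -2  -1   3  -4   3  -3   0   2   1   1   4   5  -2  -1   0  -3  -1
   54 S   2  -4   4   1  -3   3   1   4  -2   3   2  -2  -2   0  -1   3   1   2  -3  -2
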