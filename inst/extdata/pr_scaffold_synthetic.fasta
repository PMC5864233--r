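>PR_scaffold_synthetic designed proteorhodopsin-architecture scaffold (synthetic); DTE-L motif at 97/101/105/108, retinal lysine 298
MKVLIILLVLLILIVFLLIILFIIVLFILLIFVKNENNQENENEQEQILLVLIVLVVLLL
LIILVVVLIIFIVVLIIIRENQDENRNQRRERVILIDVLVTVVLLLLEIVIILVVVLILV
LIILVILIVILVIQDRQQQQRNEDRQEVLLLVLIVLLIILLVIFVVLLLVLVVLLLILRR
NNDRNEKEQNNQLVVIVILVVVIVIVILVVIVLVILLLFLFILDDQNERKKKEQRQELLL
IIVIIIILILLLIFILIVIIVLVLIVVLDRQQKNDNQKENDQVIVIIVVFIIIFLLFKVV
LFIVVILIFLVIIRRNQDD
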