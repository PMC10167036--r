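>ADH_seed synthetic ADH-like seed (arbitrary fixed composition)
PNVRPKTALDSESLNPQESSTLITSSLYDKVDRCVPDAKVNKKECPLCTQKNVGFSKGRP
WQSGTSTIKNQQTSSGLRDAIVNLVTQWICTWMWLIIRAVYPALRGKFPVLKLPGIFLNA
FCELVNRVVLFLEMTRLIGKTLGSDLPLSGAYLILILGQYLCKRVVGTVLEYDTTSELGM
GSINGRSKAGTVQRVLTSNVAAPKFCAEEFMIGPAGGLLVNVKPIMLRIVDQRSLNKAVA
LTPFIFKKSSVAVALAGPIVDDLEYWYCSQAGPTLTVKAETWPINFQKDLTFDFQIDPYP
NRPGPLQHTPKIDAENVLRLLLLLKLDHLATDSTSDKGKHAFSGQGERLL
PNVRPKTALDSESLNPQESSTLITSSLYDKVDRCVPDAKVNKKECPLCTQKNVGFSKGRPWQSGTSTIKNQQTSSGLRDAIVNLVTQWICTWMWLIIRAVYPALRGKFPVLKLPGIFLNAFCELVNRVVLFLEMTRLIGKTLGSDLPLSGAYLILILGQYLCKRVVGTVLEYDTTSELGMGSINGRSKAGTVQRVLTSNVAAPKFCAEEFMIGPAGGLLVNVKPIMLRIVDQRSLNKAVALTPFIFKKSSVAVALAGPIVDDLEYWYCSQAGPTLTVKAETWPINFQKDLTFDFQIDPYPNRPGPLQHTPKIDAENVLRLLLLLKLDHLATDSTSDKGKHAFSGQGERLL
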