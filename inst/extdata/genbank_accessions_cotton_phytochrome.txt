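HM143735
HM143736
HM143737
HM143738
HM143739
HM143740
HM143741
HM143742
HM143743
HM143744
HM143745
HM143746
HM143747
HM143748
HM143749
HM143750
HM143751
HM143752
HM143753
HM143754
HM143755
HM143756
HM143757
HM143758
HM143759
HM143760
HM143761
HM143762
HM143763
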