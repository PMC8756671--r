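>GH1_BGL_REF_SYN synthetic glucose-tolerant GH1 beta-glucosidase reference (Trp168/Leu173)
MVIEMRNVGSKVQTLDSMERATSASKALGSLPYLGRRMYDSSLMPLTSGNNGFSLHKRTY
PISDADLTCATIEADSPAGILRISAIDWDEYHSATSGVLDSTVEIAATMNELDTTAPQQY
GLGALANIMAAIKGQKFRMSASGRVTGNQEFFIETGNGNSRETFNEPWQDAYLERTPEVV
ILALLIEHWGRISSVFQSIAPPVMYDNDNGKAVGMKRRTDDFGLAHKEFYNSPDAAMIWI
LGLHEDQVTGVEGSHVLAPCNDDDNSFANLTMNVASAKGNGSPNQACDIALSRTSDSEFD
DVRVRAEGARLDVAQCLGGSLGADMSRGMELLGDVKGTSDPDLARHQMEQLKLENMVEYA
ELNQFEAVVAEDNQSIVKNMEDEGPDSITENGENQGVVLGRILEKVIQRYSEAQTSRSGM
NFRPSVDRRDLEDPPMRMVVVGTIYGT
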